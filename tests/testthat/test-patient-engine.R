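# Virtual-patient dynamics: calibration, action effects, determinism.

test_that("initialization sets the arrival state", {
  state <- engine_init(default_scenario())
  expect_equal(state$time, 0)
  expect_equal(state$blood_volume, 1.0)
  expect_true(state$alive)
  expect_identical(unclass(state$vitals),
                   unclass(default_scenario()$initial_vitals))
})

test_that("a dead-on-arrival scenario is rejected", {
  s <- default_scenario()
  s$initial_vitals[["spo2"]] <- 65   # below the lethal bound of 70
  expect_error(engine_init(s), class = "traumasim_validation_error")
})

test_that("untreated death occurs at remaining_lifetime within one tick", {
  for (lifetime in c(60, 240)) {
    s <- quick_scenario(lifetime)
    log <- run_session(s, data.frame(action_id = character(),
                                     time = numeric()),
                       horizon = lifetime + 5)
    expect_equal(log$terminal$outcome, "dead")
    expect_lte(abs(log$terminal$end_time - lifetime), 1)
  }
})

test_that("untreated death time matches randomized scenarios (property)", {
  set.seed(71)
  for (i in 1:20) {
    lifetime <- sample(40:400, 1)
    s <- trauma_scenario(
      scenario_id = "pelvic_trauma_default",
      profile = patient_profile(sample(c("male", "female"), 1),
                                sample(18:90, 1)),
      initial_vitals = vital_signs(
        heart_rate = runif(1, 70, 140),
        systolic_bp = runif(1, 85, 140),
        diastolic_bp = runif(1, 45, 80),
        spo2 = runif(1, 80, 99),
        respiratory_rate = runif(1, 12, 30),
        temperature = runif(1, 32, 37),
        consciousness = sample(8:15, 1)
      ),
      remaining_lifetime = lifetime
    )
    log <- run_session(s, data.frame(action_id = character(),
                                     time = numeric()),
                       horizon = lifetime + 5)
    expect_equal(log$terminal$outcome, "dead")
    expect_lte(abs(log$terminal$end_time - lifetime), 1)
  }
})

test_that("untreated vitals follow the closed-form line before any crossing", {
  s <- quick_scenario(100)
  cfg <- engine_config()
  state <- engine_init(s, cfg)
  v0 <- s$initial_vitals
  slope_spo2 <- (s$lethal_bounds$spo2[1] - v0[["spo2"]]) / 100
  slope_temp <- (s$lethal_bounds$temperature[1] - v0[["temperature"]]) / 100
  bleed <- state$bleeding_rate
  for (t in 1:50) {
    state <- engine_step(state, cfg)
    expect_equal(unname(state$vitals[["spo2"]]), v0[["spo2"]] + slope_spo2 * t,
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unname(state$vitals[["temperature"]]),
                 v0[["temperature"]] + slope_temp * t,
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unname(state$vitals[["systolic_bp"]]),
                 v0[["systolic_bp"]] - cfg$sbp_per_volume * bleed * t,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("a zero-slope stable state is a fixed point of the tick", {
  s <- quick_scenario(60)
  cfg <- engine_config()
  state <- engine_init(s, cfg)
  state$slopes[] <- 0
  state$bleeding_rate <- 0
  before <- state$vitals
  state <- engine_step(state, cfg)
  expect_identical(state$vitals, before)
  expect_equal(state$blood_volume, 1.0)
})

test_that("death is absorbing: stepping or acting on a dead patient errors", {
  s <- quick_scenario(40)
  cfg <- engine_config()
  state <- engine_init(s, cfg)
  while (state$alive) state <- engine_step(state, cfg)
  expect_error(engine_step(state, cfg), class = "traumasim_state_error")
  expect_error(apply_action(state, "oxygenation", cfg),
               class = "traumasim_state_error")
})

test_that("additive effects clip at physiological caps", {
  s <- quick_scenario(200, spo2 = 95)
  state <- engine_init(s)
  res <- apply_action(state, "oxygenation")  # +10 on spo2 95
  expect_equal(unname(res$state$vitals[["spo2"]]), 100)
  expect_equal(unname(res$record$vitals_before[["spo2"]]), 95)
})

test_that("unknown actions and over-repetition are errors", {
  state <- engine_init(quick_scenario(200))
  expect_error(apply_action(state, "defibrillation"),
               class = "traumasim_validation_error")
  res <- apply_action(state, "pelvic_binder")
  expect_error(apply_action(res$state, "pelvic_binder"),
               class = "traumasim_validation_error")
})

test_that("fluids gain more volume once the binder controls the bleed", {
  s <- default_scenario()
  cfg <- engine_config()
  run_to <- function(with_binder) {
    state <- engine_init(s, cfg)
    if (with_binder) state <- apply_action(state, "pelvic_binder", cfg)$state
    for (t in 1:10) state <- engine_step(state, cfg)
    before <- state$blood_volume
    state <- apply_action(state, "crystalloids", cfg)$state
    state$blood_volume - before
  }
  gain_binder <- run_to(TRUE)
  gain_none <- run_to(FALSE)
  expect_gt(gain_binder, gain_none)
  expect_equal(gain_binder, 0.10)         # full efficiency
  expect_equal(gain_none, 0.10 * 0.2)     # uncontrolled: 20% retained
})

test_that("earlier binder placement never yields lower blood volume later", {
  s <- default_scenario()
  cfg <- engine_config()
  volume_at <- function(binder_time, upto = 120) {
    state <- engine_init(s, cfg)
    out <- numeric(upto)
    for (t in seq_len(upto)) {
      if (t - 1 == binder_time) {
        state <- apply_action(state, "pelvic_binder", cfg)$state
      }
      state <- engine_step(state, cfg)
      out[t] <- state$blood_volume
    }
    out
  }
  early <- volume_at(0)
  late <- volume_at(60)
  expect_true(all(early >= late - 1e-12))
  expect_gt(early[120], late[120])
})

test_that("session replay is deterministic and ties favor the action", {
  s <- default_scenario()
  script <- data.frame(
    action_id = c("airway_inspection", "oxygenation", "pelvic_binder"),
    time = c(0, 5, 10)
  )
  l1 <- run_session(s, script)
  l2 <- run_session(s, script)
  expect_identical(l1, l2)
  # the action scheduled at t = 10 sees the state of minute 10 before that
  # minute's deterioration is applied
  ev <- l1$events[[3]]
  expect_equal(ev$time, 10)
  state <- engine_init(s)
  for (t in 1:10) state <- engine_step(state, engine_config())
  expect_equal(unname(ev$vitals_before[["systolic_bp"]]),
               unname(state$vitals[["systolic_bp"]]))
})

test_that("scripts beyond the horizon or malformed are rejected", {
  s <- quick_scenario(60)
  expect_error(
    run_session(s, data.frame(action_id = "oxygenation", time = 300)),
    class = "traumasim_validation_error"
  )
  expect_error(
    run_session(s, data.frame(action_id = c("a", "b"), time = c(5, 2))),
    class = "traumasim_format_error"
  )
  expect_error(run_session(s, list(1, 2)), class = "traumasim_format_error")
})

test_that("every complete reference sequence executed promptly survives", {
  model <- default_reference_model()
  seqs <- enumerate_sequences(model)
  set.seed(5)
  picks <- c(which.min(lengths(seqs)), which.max(lengths(seqs)),
             sample(length(seqs), 6))
  for (k in picks) {
    ref <- seqs[[k]]
    script <- data.frame(action_id = ref,
                         time = seq(0, by = 2, length.out = length(ref)))
    log <- run_session(default_scenario(), script)
    expect_equal(log$terminal$outcome, "alive")
  }
})
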
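# Session metrics, cohort summaries, report generation, log persistence.

test_that("a session equal to a reference sequence scores perfectly", {
  model <- default_reference_model()
  seqs <- enumerate_sequences(model)
  ref <- seqs[[which(lengths(seqs) == 8)[1]]]
  m <- score_session(manual_log(ref), model)
  expect_equal(m$n_actions, 8)
  expect_equal(m$n_correct, 8)
  expect_equal(m$n_sequential, 8)
})

test_that("an empty but valid log scores zero on all counts", {
  log <- manual_log(character())
  m <- score_session(log)
  expect_equal(m$n_actions, 0)
  expect_equal(m$n_correct, 0)
  expect_equal(m$n_sequential, 0)
  expect_equal(m$treatment_time, 240)
  expect_true(all(!m$per_action$performed))
})

test_that("malformed logs are rejected at construction", {
  expect_error(
    manual_log("airway_inspection", end_time = 0.5),  # before last event
    class = "traumasim_validation_error"
  )
  v <- vital_signs(110, 100, 65, 93, 22, 34.5, 13)
  bad_events <- list(
    list(action_id = "a", time = 5, vitals_before = v, vitals_after = v),
    list(action_id = "b", time = 2, vitals_before = v, vitals_after = v)
  )
  expect_error(
    event_log("x", "s", "t", "student", bad_events,
              list(outcome = "alive", end_time = 10)),
    class = "traumasim_validation_error"
  )
})

test_that("scoring agrees with exhaustive oracles on short logs (property)", {
  cat <- toy_catalog()
  toy_model <- reference_model(list(
    ref_slot("mandatory", "a", "A"),
    ref_slot("optional", "b", "A"),
    ref_slot("alternative", c("c", "d"), "B"),
    ref_slot("repeatable", "e", "D", max_extra = 1),
    ref_slot("mandatory", "f", "E")
  ), cat)
  refs <- enumerate_sequences(toy_model)
  ids <- names(cat)
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(0:8, 1)
    actions <- if (n) sample(ids, n, replace = TRUE) else character()
    m <- score_session(manual_log(actions), toy_model)
    want_correct <- if (n) max(vapply(refs, oracle_lcs, integer(1), a = actions)) else 0L
    want_seq <- if (n) max(vapply(refs, oracle_substring, integer(1), a = actions)) else 0L
    expect_equal(m$n_correct, want_correct)
    expect_equal(m$n_sequential, want_seq)
    expect_lte(m$n_sequential, m$n_correct)
    expect_lte(m$n_correct, m$n_actions)
  }
})

test_that("the metric ordering holds on random full-catalog logs (property)", {
  model <- default_reference_model()
  ids <- names(model$catalog)
  set.seed(47)
  for (rep in 1:25) {
    n <- sample(1:14, 1)
    m <- score_session(manual_log(sample(ids, n, replace = TRUE)), model)
    expect_lte(m$n_sequential, m$n_correct)
    expect_lte(m$n_correct, m$n_actions)
    expect_gte(m$treatment_time, 0)
  }
})

test_that("a frozen hand-checked example scores as expected", {
  # Against reference (a, b, c, e, f): log (a, c, b, e) shares the
  # subsequence (a, c, e) (or (a, b, e)) -> n_correct 3, but no two-action
  # block of the log occurs contiguously in the reference -> n_sequential 1.
  cat <- toy_catalog()
  model <- reference_model(list(
    ref_slot("mandatory", "a", "A"),
    ref_slot("mandatory", "b", "A"),
    ref_slot("mandatory", "c", "B"),
    ref_slot("mandatory", "e", "D"),
    ref_slot("mandatory", "f", "E")
  ), cat)
  m <- score_session(manual_log(c("a", "c", "b", "e")), model)
  expect_equal(m$n_actions, 4)
  expect_equal(m$n_correct, 3)
  expect_equal(m$n_sequential, 1)
})

test_that("cohort metrics reproduce hand-computed means and SDs", {
  model <- default_reference_model()
  seqs <- enumerate_sequences(model)
  ref <- seqs[[1]]
  lens <- c(2, 4, 6, 8, 3)
  logs <- lapply(seq_along(lens), function(i) {
    manual_log(ref[seq_len(lens[i])], trainee = paste0("s", i),
               end_time = 100 + i)
  })
  cm <- cohort_metrics(logs, model)
  num <- cm$numeric
  na <- num[num$metric == "n_actions", ]
  expect_equal(na$mean, mean(lens))
  expect_equal(na$sd, sd(lens))
  tt <- num[num$metric == "treatment_time", ]
  expect_equal(tt$mean, mean(101:105))
})

test_that("single-session groups report SD 0 and are flagged", {
  logs <- list(manual_log(c("airway_inspection"), group = "doctor"))
  cm <- cohort_metrics(logs)
  expect_true(all(cm$numeric$sd == 0))
  expect_match(cm$flags, "single session")
  expect_error(cohort_metrics(list()), class = "traumasim_validation_error")
})

test_that("per-action percentages use half-up integer rounding", {
  # 20 of 28 students performing airway inspection prints as 71% (20/28)
  logs <- lapply(1:28, function(i) {
    acts <- if (i <= 20) "airway_inspection" else "oxygenation"
    manual_log(acts, trainee = paste0("s", i))
  })
  cm <- cohort_metrics(logs)
  a <- cm$actions
  expect_equal(a$formatted[a$action_id == "airway_inspection"], "71% (20/28)")
  expect_equal(a$formatted[a$action_id == "oxygenation"], "29% (8/28)")
})

test_that("reports are complete, deterministic, and round-trip", {
  log <- perfect_session()
  m <- score_session(log)
  r1 <- generate_report(log, m)
  r2 <- generate_report(log, m)
  expect_identical(r1, r2)
  expect_equal(length(gregexpr("- t=", r1$markdown)[[1]]), length(log$events))
  parsed <- parse_report(r1$json)
  expect_equal(parsed$n_actions, m$n_actions)
  expect_equal(parsed$n_correct, m$n_correct)
  expect_equal(parsed$n_sequential, m$n_sequential)
  expect_equal(parsed$treatment_time, m$treatment_time)
  expect_equal(parsed$per_action, m$per_action)
})

test_that("mismatched log and metrics are refused", {
  log1 <- manual_log("airway_inspection", trainee = "t1")
  log2 <- manual_log("airway_inspection", trainee = "t2")
  m2 <- score_session(log2)
  expect_error(generate_report(log1, m2),
               class = "traumasim_validation_error")
})

test_that("event logs round-trip through JSONL", {
  log <- perfect_session()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(log, path)
  back <- read_event_log(path)
  expect_equal(back$log_id, log$log_id)
  expect_equal(length(back$events), length(log$events))
  expect_equal(back$terminal, log$terminal)
  expect_equal(
    vapply(back$events, `[[`, character(1), "action_id"),
    vapply(log$events, `[[`, character(1), "action_id")
  )
  v1 <- back$events[[1]]$vitals_after
  v2 <- log$events[[1]]$vitals_after
  expect_equal(as.numeric(v1), as.numeric(v2[names(v1)]))
})
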
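# Discrete-time virtual-patient engine.
#
# Untreated dynamics are linear per vital, calibrated so that the first
# lethal-bound crossing happens at exactly the scenario's remaining
# lifetime. Hemorrhage is the primary lethal mechanism of the pelvic case:
# blood volume falls at a calibrated bleeding rate and drives systolic /
# diastolic pressure down and heart rate up through linear couplings.
# SpO2, temperature and respiratory rate deteriorate independently, also
# calibrated to cross their bounds at the remaining lifetime; consciousness
# declines at half pace and never reaches a lethal level within the
# session. Actions apply additive deltas instantly (with physiological
# clipping) and may multiply a vital's deterioration rate or the bleeding
# rate.

#' Engine configuration
#'
#' Tunable constants of the patient dynamics.
#'
#' @param tick Minutes per simulation step (default 1).
#' @param binder_bleeding_factor Multiplier applied to the bleeding rate
#'   when the pelvic binder is placed (default 0.1).
#' @param uncontrolled_fluid_efficiency Fraction of infused volume
#'   retained while the hemorrhage is uncontrolled (default 0.2); infused
#'   fluids are fully retained once bleeding is controlled. Encodes the
#'   futility of volume resuscitation before mechanical hemorrhage
#'   control: most of the infused volume is lost through the bleed.
#' @param controlled_fraction Bleeding counts as controlled when the
#'   current rate falls below this fraction of the initial calibrated rate
#'   (default 0.5).
#' @param sbp_per_volume mmHg of systolic pressure lost per unit fraction
#'   of blood volume lost (default 100).
#' @param dbp_per_volume Same coupling for diastolic pressure (default 50).
#' @param hr_per_volume bpm of heart-rate rise per unit fraction of volume
#'   lost (default 60).
#' @param consciousness_lifetime_factor Consciousness declines toward its
#'   floor over this multiple of the remaining lifetime (default 2, i.e.
#'   half the pace of the lethal vitals).
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(tick = 1,
                          binder_bleeding_factor = 0.1,
                          uncontrolled_fluid_efficiency = 0.2,
                          controlled_fraction = 0.5,
                          sbp_per_volume = 100,
                          dbp_per_volume = 50,
                          hr_per_volume = 60,
                          consciousness_lifetime_factor = 2) {
  problems <- character()
  if (!is_scalar_number(tick) || tick <= 0) {
    problems <- c(problems, "tick must be > 0 minutes")
  }
  for (nm in c("binder_bleeding_factor", "uncontrolled_fluid_efficiency",
               "controlled_fraction")) {
    val <- get(nm)
    if (!is_scalar_number(val) || val < 0 || val > 1) {
      problems <- c(problems, sprintf("%s must lie in [0, 1]", nm))
    }
  }
  if (!is_scalar_number(sbp_per_volume) || sbp_per_volume <= 0) {
    problems <- c(problems, "sbp_per_volume must be > 0")
  }
  if (length(problems)) validation_error(problems)
  structure(
    list(
      tick = tick,
      binder_bleeding_factor = binder_bleeding_factor,
      uncontrolled_fluid_efficiency = uncontrolled_fluid_efficiency,
      controlled_fraction = controlled_fraction,
      sbp_per_volume = sbp_per_volume,
      dbp_per_volume = dbp_per_volume,
      hr_per_volume = hr_per_volume,
      consciousness_lifetime_factor = consciousness_lifetime_factor
    ),
    class = "engine_config"
  )
}

clip_vital <- function(name, value) {
  r <- PHYS_RANGE[[name]]
  min(max(value, r[1]), r[2])
}

vital_dead <- function(vitals, bounds) {
  for (nm in VITAL_NAMES) {
    b <- bounds[[nm]]
    if (vitals[[nm]] <= b[1] || vitals[[nm]] >= b[2]) return(TRUE)
  }
  FALSE
}

#' Initialize the simulation state
#'
#' Calibrates the deterioration profile from the scenario: the bleeding
#' rate is set so that, through the blood-pressure coupling, systolic
#' pressure reaches its lethal bound at exactly `remaining_lifetime`
#' minutes; SpO2, temperature and respiratory rate receive linear slopes
#' crossing their bounds at the same time; consciousness declines at a
#' slower, non-lethal pace.
#'
#' @param scenario A valid [trauma_scenario()].
#' @param config An [engine_config()].
#' @return A list of class `simulation_state` with fields `time`, `vitals`,
#'   `blood_volume`, `bleeding_rate`, `alive`, `slopes`, `rate_mult` and
#'   `active_modifiers`.
#' @export
engine_init <- function(scenario, config = engine_config()) {
  if (!inherits(scenario, "trauma_scenario")) {
    validation_error("engine_init expects a trauma_scenario")
  }
  v0 <- scenario$initial_vitals
  bounds <- scenario$lethal_bounds
  if (!vitals_inside_bounds(v0, bounds)) {
    validation_error("initial vitals outside lethal bounds: dead on arrival")
  }
  T_death <- scenario$remaining_lifetime

  bleeding_rate <- (v0[["systolic_bp"]] - bounds$systolic_bp[1]) /
    (config$sbp_per_volume * T_death)

  # Volume fraction lost at the moment systolic pressure turns lethal.
  # The diastolic and heart-rate couplings are clamped per scenario so
  # that neither crosses its own bound before systolic pressure does:
  # hemorrhagic death is declared by systolic collapse at T_death.
  lost_at_death <- bleeding_rate * T_death
  dbp_coupling <- min(config$dbp_per_volume,
                      (v0[["diastolic_bp"]] - bounds$diastolic_bp[1]) /
                        lost_at_death)
  hr_coupling <- min(config$hr_per_volume,
                     (bounds$heart_rate[2] - v0[["heart_rate"]]) /
                       lost_at_death)

  slopes <- stats::setNames(numeric(length(VITAL_NAMES)), VITAL_NAMES)
  slopes[["spo2"]] <- (bounds$spo2[1] - v0[["spo2"]]) / T_death
  slopes[["temperature"]] <- (bounds$temperature[1] - v0[["temperature"]]) /
    T_death
  slopes[["respiratory_rate"]] <-
    (bounds$respiratory_rate[2] - v0[["respiratory_rate"]]) / T_death
  slopes[["consciousness"]] <-
    (PHYS_RANGE$consciousness[1] - v0[["consciousness"]]) /
    (config$consciousness_lifetime_factor * T_death)
  # heart_rate / systolic_bp / diastolic_bp move through the blood-volume
  # coupling, not through an independent slope.

  structure(
    list(
      scenario_id = scenario$scenario_id,
      time = 0,
      vitals = v0,
      blood_volume = 1.0,
      bleeding_rate = bleeding_rate,
      initial_bleeding_rate = bleeding_rate,
      alive = TRUE,
      death_time = NA_real_,
      slopes = slopes,
      couplings = c(systolic_bp = config$sbp_per_volume,
                    diastolic_bp = dbp_coupling,
                    heart_rate = hr_coupling),
      rate_mult = stats::setNames(rep(1, length(VITAL_NAMES)), VITAL_NAMES),
      active_modifiers = list(),
      action_counts = integer(),
      bounds = bounds
    ),
    class = "simulation_state"
  )
}

# Shift the hemodynamic vitals in response to a blood-volume change dbv
# (fraction of normal volume; negative = loss), with clipping. Couplings
# come from the state: they are calibrated per scenario at initialization.
apply_volume_coupling <- function(state, dbv, config) {
  k <- state$couplings
  v <- state$vitals
  v[["systolic_bp"]] <- clip_vital("systolic_bp",
                                   v[["systolic_bp"]] + k[["systolic_bp"]] * dbv)
  v[["diastolic_bp"]] <- clip_vital("diastolic_bp",
                                    v[["diastolic_bp"]] + k[["diastolic_bp"]] * dbv)
  v[["heart_rate"]] <- clip_vital("heart_rate",
                                  v[["heart_rate"]] - k[["heart_rate"]] * dbv)
  state$vitals <- v
  state
}

#' Advance the simulation by one tick
#'
#' Time moves forward by `config$tick` minutes: blood volume falls by
#' `bleeding_rate * tick` (driving pressure and heart rate through the
#' configured couplings), independently deteriorating vitals move along
#' their possibly modifier-adjusted slopes, and the patient dies the first
#' tick any vital reaches or exits its lethal bounds. Death is absorbing;
#' stepping a dead patient is an error.
#'
#' @param state A `simulation_state` with `alive = TRUE`.
#' @param config The [engine_config()] used at initialization.
#' @return The advanced `simulation_state`.
#' @export
engine_step <- function(state, config = engine_config()) {
  if (!isTRUE(state$alive)) {
    state_error("cannot step: the patient is dead (absorbing state)")
  }
  tick <- config$tick
  bv_new <- max(0, state$blood_volume - state$bleeding_rate * tick)
  dbv <- bv_new - state$blood_volume
  state$blood_volume <- bv_new
  state <- apply_volume_coupling(state, dbv, config)
  for (nm in c("spo2", "temperature", "respiratory_rate", "consciousness")) {
    state$vitals[[nm]] <- clip_vital(
      nm, state$vitals[[nm]] + state$slopes[[nm]] * state$rate_mult[[nm]] * tick
    )
  }
  state$time <- state$time + tick
  if (vital_dead(state$vitals, state$bounds)) {
    state$alive <- FALSE
    state$death_time <- state$time
  }
  state
}

#' Apply a treatment action to the patient
#'
#' Additive deltas are applied instantly with physiological clipping (SpO2
#' is capped at 100, temperature at 37.5, and so on); rate multipliers are
#' registered persistently. The pelvic binder multiplies the bleeding rate
#' by `config$binder_bleeding_factor`. Fluid actions (crystalloids, blood
#' transfusion) add volume scaled by `config$uncontrolled_fluid_efficiency`
#' while the bleeding rate exceeds the controlled threshold, and at full
#' efficiency otherwise.
#'
#' @param state A living `simulation_state`.
#' @param action An `action_definition` or an action_id resolvable in
#'   `catalog`.
#' @param config The [engine_config()].
#' @param catalog Action catalog (default: the built-in catalog).
#' @return A list with fields `state` (the updated state) and `record` (the
#'   effect record: action, time, vitals and blood volume before/after).
#' @export
apply_action <- function(state, action, config = engine_config(),
                         catalog = default_action_catalog()) {
  if (!isTRUE(state$alive)) {
    state_error("cannot act: the patient is dead")
  }
  if (is.character(action)) {
    if (!action %in% names(catalog)) {
      validation_error(sprintf("unknown action_id '%s'", action))
    }
    action <- catalog[[action]]
  }
  if (!inherits(action, "action_definition")) {
    validation_error("action must be an action_definition or an action_id")
  }
  id <- action$action_id
  count <- state$action_counts[id]
  if (is.na(count)) count <- 0L
  if (count >= action$repeatable) {
    validation_error(sprintf(
      "action '%s' already applied %d time(s); maximum is %d",
      id, count, action$repeatable
    ))
  }

  before <- list(vitals = state$vitals, blood_volume = state$blood_volume,
                 bleeding_rate = state$bleeding_rate)

  for (eff in action$effects) {
    if (eff$vital == "bleeding_rate") {
      factor <- if (id == "pelvic_binder") config$binder_bleeding_factor
                else eff$mult
      state$bleeding_rate <- state$bleeding_rate * factor
    } else if (eff$vital == "blood_volume") {
      uncontrolled <- state$bleeding_rate >
        config$controlled_fraction * state$initial_bleeding_rate
      efficiency <- if (uncontrolled) config$uncontrolled_fluid_efficiency
                    else 1
      dbv <- min(eff$delta * efficiency, 1.2 - state$blood_volume)
      if (dbv != 0) {
        state$blood_volume <- state$blood_volume + dbv
        state <- apply_volume_coupling(state, dbv, config)
      }
    } else {
      state$vitals[[eff$vital]] <- clip_vital(
        eff$vital, state$vitals[[eff$vital]] + eff$delta
      )
      if (eff$mult != 1) {
        state$rate_mult[[eff$vital]] <- state$rate_mult[[eff$vital]] * eff$mult
      }
    }
  }
  mults <- vapply(action$effects, `[[`, numeric(1), "mult")
  if (any(mults != 1)) {
    state$active_modifiers[[length(state$active_modifiers) + 1L]] <- list(
      action_id = id,
      targets = vapply(action$effects[mults != 1], `[[`, character(1), "vital"),
      mult = mults[mults != 1]
    )
  }
  state$action_counts[id] <- count + 1L

  record <- list(
    action_id = id,
    time = state$time,
    vitals_before = before$vitals,
    vitals_after = state$vitals,
    blood_volume_before = before$blood_volume,
    blood_volume_after = state$blood_volume,
    bleeding_rate_before = before$bleeding_rate,
    bleeding_rate_after = state$bleeding_rate
  )
  list(state = state, record = record)
}

#' Replay a scripted session deterministically
#'
#' Interleaves scheduled actions with deterioration ticks: at each integer
#' simulated minute, all actions scheduled at that minute are applied
#' first (trainee input precedes passive deterioration at the same
#' timestamp), then the engine steps one tick. The replay ends at the
#' patient's death or at `horizon` minutes, whichever comes first.
#' Identical inputs yield identical logs.
#'
#' @param scenario A [trauma_scenario()].
#' @param script A data.frame with columns `action_id` and `time` (minutes,
#'   non-decreasing, within `[0, horizon]`). An empty script replays pure
#'   untreated deterioration.
#' @param config An [engine_config()].
#' @param horizon Session length in minutes; defaults to the scenario's
#'   remaining lifetime.
#' @param trainee_id,group Metadata copied into the resulting log.
#' @return An [event_log()] with one event per applied action and a
#'   terminal record (`alive` at `horizon`, or `dead` at the death time).
#' @export
run_session <- function(scenario, script, config = engine_config(),
                        horizon = NULL, trainee_id = "anonymous",
                        group = "student") {
  if (is.null(horizon)) horizon <- scenario$remaining_lifetime
  if (!is.data.frame(script) ||
      !all(c("action_id", "time") %in% names(script))) {
    format_error("script must be a data.frame with columns action_id, time")
  }
  if (nrow(script) > 0) {
    if (!is.numeric(script$time) || any(!is.finite(script$time)) ||
        any(script$time < 0)) {
      format_error("script times must be finite and >= 0")
    }
    if (is.unsorted(script$time)) {
      format_error("script times must be non-decreasing")
    }
    if (any(script$time > horizon)) {
      validation_error(sprintf(
        "script schedules actions beyond the %g-minute horizon", horizon
      ))
    }
  }
  catalog <- resolve_catalog(scenario$catalog_id)
  if (nrow(script) > 0 && !all(script$action_id %in% names(catalog))) {
    bad <- setdiff(unique(script$action_id), names(catalog))
    validation_error(sprintf("unknown action_id(s) in script: %s",
                             paste(bad, collapse = ", ")))
  }

  state <- engine_init(scenario, config)
  # Actions land on the tick grid: an action at time t applies at the first
  # grid point >= t, before that tick's deterioration.
  sched <- if (nrow(script)) ceiling(script$time / config$tick) * config$tick
           else numeric()
  events <- vector("list", nrow(script))
  n_ev <- 0L
  i <- 1L

  repeat {
    while (i <= length(sched) && sched[i] <= state$time && state$alive) {
      res <- apply_action(state, script$action_id[i], config, catalog)
      state <- res$state
      n_ev <- n_ev + 1L
      events[[n_ev]] <- res$record
      i <- i + 1L
    }
    if (!state$alive || state$time >= horizon) break
    state <- engine_step(state, config)
  }

  terminal <- list(
    outcome = if (state$alive) "alive" else "dead",
    end_time = if (state$alive) horizon else state$death_time
  )
  event_log(
    log_id = paste(scenario$scenario_id, trainee_id, sep = "__"),
    scenario_id = scenario$scenario_id,
    trainee_id = trainee_id,
    group = group,
    events = events[seq_len(n_ev)],
    terminal = terminal
  )
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation_state t=%g min, %s>\n", x$time,
              if (x$alive) "alive" else sprintf("dead at %g", x$death_time)))
  cat(sprintf("  blood volume %.3f (bleeding %.5f/min)\n",
              x$blood_volume, x$bleeding_rate))
  v <- x$vitals
  cat(sprintf(
    "  HR %.1f, BP %.1f/%.1f, SpO2 %.1f, RR %.1f, T %.2f, consciousness %.1f\n",
    v[["heart_rate"]], v[["systolic_bp"]], v[["diastolic_bp"]], v[["spo2"]],
    v[["respiratory_rate"]], v[["temperature"]], v[["consciousness"]]
  ))
  invisible(x)
}
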
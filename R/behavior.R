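# Synthetic trainee-behavior generator.
#
# Stands in for human participants: each synthetic trainee walks the
# reference grammar, includes each action with its group's per-action
# performance probability, perturbs the ordering according to an
# adherence parameter, and receives log-normal action times. The default
# profiles encode the published per-action performance proportions of the
# 28-student and 13-doctor pilot cohorts, so the full pipeline
# (generate_cohort -> run_session -> score_session -> cohort_metrics) can
# be exercised end to end without human data.
#
# Sampling model for a slot with branch probabilities p_i (a non-
# alternative slot is a single branch): the slot fires with probability
# min(1, sum(p_i)) and the branch is chosen proportionally to p_i. When
# sum(p_i) <= 1 every action's marginal performance probability is
# exactly its profile value, which is what makes large-cohort parameter
# recovery exact; it also makes mutually exclusive alternatives (e.g. the
# two warming measures) sum to the observed union proportion.

#' Construct a trainee behavior profile
#'
#' @param label Group label, canonically `"student"` or `"doctor"`.
#' @param actions A data.frame with columns `action_id`, `prob`
#'   (performance probability in \[0, 1\]), `t_median` (timing median,
#'   minutes > 0) and `t_sigma` (log-normal dispersion > 0).
#' @param adherence Probability of following the reference order at each
#'   step of the script, in \[0, 1\].
#' @param extra_repeat_prob For repeatable slots, the probability of each
#'   allowed extra repetition (default 0.3).
#' @return A list of class `behavior_profile`.
#' @export
behavior_profile <- function(label, actions, adherence,
                             extra_repeat_prob = 0.3) {
  problems <- character()
  if (!is_scalar_string(label)) {
    problems <- c(problems, "label must be a non-empty string")
  }
  needed <- c("action_id", "prob", "t_median", "t_sigma")
  if (!is.data.frame(actions) || !all(needed %in% names(actions))) {
    problems <- c(problems, sprintf(
      "actions must be a data.frame with columns: %s",
      paste(needed, collapse = ", ")
    ))
  } else {
    if (any(actions$prob < 0 | actions$prob > 1 | is.na(actions$prob))) {
      problems <- c(problems, "performance probabilities must lie in [0, 1]")
    }
    if (any(actions$t_median <= 0 | is.na(actions$t_median))) {
      problems <- c(problems, "timing medians must be > 0 minutes")
    }
    if (any(actions$t_sigma <= 0 | is.na(actions$t_sigma))) {
      problems <- c(problems, "timing dispersions must be > 0")
    }
    if (anyDuplicated(actions$action_id)) {
      problems <- c(problems, "action_ids must be unique in a profile")
    }
  }
  if (!is_scalar_number(adherence) || adherence < 0 || adherence > 1) {
    problems <- c(problems, "adherence must lie in [0, 1]")
  }
  if (!is_scalar_number(extra_repeat_prob) || extra_repeat_prob < 0 ||
      extra_repeat_prob > 1) {
    problems <- c(problems, "extra_repeat_prob must lie in [0, 1]")
  }
  if (length(problems)) validation_error(problems)
  structure(
    list(label = label, actions = actions, adherence = adherence,
         extra_repeat_prob = extra_repeat_prob),
    class = "behavior_profile"
  )
}

profile_prob <- function(profile, id) {
  i <- match(id, profile$actions$action_id)
  if (is.na(i)) 0 else profile$actions$prob[i]
}

profile_timing <- function(profile, id) {
  i <- match(id, profile$actions$action_id)
  if (is.na(i)) c(median = 60, sigma = 0.8)
  else c(median = profile$actions$t_median[i],
         sigma = profile$actions$t_sigma[i])
}

#' Default student and doctor behavior profiles
#'
#' Per-action performance probabilities equal the pilot cohorts' observed
#' fractions: e.g. student airway inspection 20/28, doctor oxygenation
#' 13/13, doctor hot liquids 8/13. The two warming measures are mutually
#' exclusive alternatives whose probabilities sum to the observed union
#' (18/28 students, 10/13 doctors). Talking to the patient has
#' probability 0 in both groups (no participant assessed disability).
#' Auxiliary grammar actions (airway clearing, vascular-access routes)
#' and all timing parameters are package defaults: timing medians are
#' anchored to the published response times where available (airway
#' inspection ~5 min students vs ~1.5 min doctors; pelvic binder medians
#' 72 vs 157 min) and invented elsewhere, with log-normal dispersion 0.8
#' (students) / 0.5 (doctors).
#'
#' @return Named list with elements `student` and `doctor`, each a
#'   [behavior_profile()].
#' @export
default_profiles <- function() {
  student <- data.frame(
    action_id = c("airway_inspection", "airway_clearing", "intubation",
                  "oxygenation", "nasal_cannula", "bag_valve_ventilation",
                  "peripheral_iv", "central_line", "pelvic_binder",
                  "blood_transfusion", "crystalloids", "talk_to_patient",
                  "thermal_blanket", "hot_liquids"),
    prob = c(20/28, 0.25, 19/28,
             27/28, 0, 0,
             0.9, 0.1, 20/28,
             24/28, 20/28, 0,
             12/28, 6/28),
    t_median = c(5, 8, 30,
                 45, 45, 45,
                 20, 25, 72,
                 90, 100, 60,
                 180, 180),
    t_sigma = 0.8,
    stringsAsFactors = FALSE
  )
  doctor <- data.frame(
    action_id = student$action_id,
    prob = c(11/13, 0.35, 7/13,
             13/13, 0, 0,
             0.7, 0.3, 10/13,
             12/13, 11/13, 0,
             2/13, 8/13),
    t_median = c(1.5, 5, 25,
                 30, 30, 30,
                 10, 15, 157,
                 100, 110, 60,
                 170, 170),
    t_sigma = 0.5,
    stringsAsFactors = FALSE
  )
  list(
    student = behavior_profile("student", student, adherence = 0.7),
    doctor = behavior_profile("doctor", doctor, adherence = 0.85)
  )
}

#' Cohort specification
#'
#' @param n_student,n_doctor Group sizes (defaults 28 and 13, the pilot
#'   cohort sizes).
#' @param scenario_id Scenario the cohort runs against.
#' @param seed Integer seed fixing all randomness.
#' @param profiles Named list with `student` and `doctor`
#'   [behavior_profile()]s.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_student = 28, n_doctor = 13,
                        scenario_id = "pelvic_trauma_default", seed = 1,
                        profiles = default_profiles()) {
  problems <- character()
  for (nm in c("n_student", "n_doctor")) {
    val <- get(nm)
    if (!is_scalar_number(val) || val < 1 || val != trunc(val)) {
      problems <- c(problems, sprintf("%s must be an integer >= 1", nm))
    }
  }
  if (!is_scalar_number(seed) || seed != trunc(seed)) {
    problems <- c(problems, "seed must be an integer")
  }
  if (!is.list(profiles) ||
      !all(c("student", "doctor") %in% names(profiles)) ||
      !all(vapply(profiles[c("student", "doctor")], inherits, logical(1),
                  "behavior_profile"))) {
    problems <- c(problems, "profiles must contain behavior_profiles
                  'student' and 'doctor'")
  }
  if (length(problems)) validation_error(problems)
  structure(
    list(n_student = as.integer(n_student), n_doctor = as.integer(n_doctor),
         scenario_id = scenario_id, seed = as.integer(seed),
         profiles = profiles),
    class = "cohort_spec"
  )
}

# Decide, slot by slot, which action instances a trainee performs.
# Returns a character vector in reference order (repeats adjacent).
sample_inclusion <- function(profile, model) {
  out <- character()
  for (slot in model$slots) {
    p <- vapply(slot$actions, profile_prob, numeric(1), profile = profile)
    s <- sum(p)
    if (s <= 0) next
    fire <- if (s >= 1) TRUE else stats::runif(1) < s
    if (!fire) next
    act <- if (length(p) == 1L) slot$actions
           else sample(slot$actions, 1L, prob = p)
    reps <- 1L
    if (slot$type == "repeatable" && slot$max_extra > 0L) {
      reps <- 1L + stats::rbinom(1L, slot$max_extra, profile$extra_repeat_prob)
    }
    out <- c(out, rep(act, reps))
  }
  out
}

# Adherence-driven order perturbation: at each step, with probability
# `adherence` take the next action in reference order, otherwise take a
# uniformly random remaining one. adherence = 1 preserves the reference
# order exactly.
perturb_order <- function(actions, adherence) {
  n <- length(actions)
  if (n <= 1L) return(actions)
  out <- character(n)
  pool <- actions
  for (k in seq_len(n)) {
    pick <- if (stats::runif(1) < adherence || length(pool) == 1L) 1L
            else sample(length(pool), 1L)
    out[k] <- pool[pick]
    pool <- pool[-pick]
  }
  out
}

#' Sample a synthetic trainee action script
#'
#' Walks the reference grammar including each action with the profile's
#' per-action probability (alternative branches chosen proportionally to
#' their probabilities), perturbs the ordering according to the
#' adherence parameter, samples one log-normal time per included action,
#' and assigns the sorted times to the perturbed order. With all
#' probabilities 1 and adherence 1, the resulting action sequence is a
#' valid reference sequence.
#'
#' Randomness is drawn from R's global generator; pass `seed` (or call
#' `set.seed()` beforehand) for reproducibility.
#'
#' @param profile A [behavior_profile()].
#' @param model A [reference_model()].
#' @param horizon Optional upper bound (minutes); sampled times are
#'   clamped to `horizon`.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `action_id` and `time` (whole
#'   minutes, non-decreasing); possibly zero rows.
#' @export
sample_script <- function(profile, model = default_reference_model(),
                          horizon = NULL, seed = NULL) {
  if (!inherits(profile, "behavior_profile")) {
    validation_error("sample_script expects a behavior_profile")
  }
  if (!is.null(seed)) set.seed(seed)
  included <- sample_inclusion(profile, model)
  build_script(included, profile, horizon)
}

build_script <- function(included, profile, horizon = NULL) {
  if (!length(included)) {
    return(data.frame(action_id = character(), time = numeric(),
                      stringsAsFactors = FALSE))
  }
  ordered <- perturb_order(included, profile$adherence)
  timing <- vapply(ordered, profile_timing, c(median = 0, sigma = 0),
                   profile = profile)
  times <- stats::rlnorm(length(ordered),
                         meanlog = log(timing["median", ]),
                         sdlog = timing["sigma", ])
  times <- sort(round(times))
  if (!is.null(horizon)) times <- pmin(times, horizon)
  data.frame(action_id = ordered, time = times, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Pinned (stratified) inclusion: each slot's per-branch count over the
# group is fixed to round_half_up(p * n) and branch assignments are
# disjoint across trainees, so the cohort's per-action k/n counts equal
# the profile's expected counts exactly.
stratified_inclusions <- function(profile, model, n) {
  per_trainee <- replicate(n, character(), simplify = FALSE)
  for (slot in model$slots) {
    p <- vapply(slot$actions, profile_prob, numeric(1), profile = profile)
    ks <- as.integer(round_half_up(p * n))
    if (sum(ks) > n) {
      validation_error(sprintf(
        "stratified counts exceed group size for slot actions: %s",
        paste(slot$actions, collapse = ", ")
      ))
    }
    idx <- sample.int(n)
    pos <- 0L
    for (j in seq_along(slot$actions)) {
      if (ks[j] == 0L) next
      who <- idx[(pos + 1L):(pos + ks[j])]
      pos <- pos + ks[j]
      for (w in who) {
        reps <- 1L
        if (slot$type == "repeatable" && slot$max_extra > 0L) {
          reps <- 1L + stats::rbinom(1L, slot$max_extra,
                                     profile$extra_repeat_prob)
        }
        per_trainee[[w]] <- c(per_trainee[[w]], rep(slot$actions[j], reps))
      }
    }
  }
  per_trainee
}

#' Generate a synthetic trainee cohort
#'
#' For each synthetic trainee, samples an action script from the group's
#' behavior profile and replays it through [run_session()]; the resulting
#' logs are tagged by group and fully reproducible from the seed. With
#' `stratified = TRUE`, per-action performance counts are pinned to
#' `round_half_up(prob * n)` per group instead of varying binomially, so
#' a (28, 13) cohort reproduces the expected k/n table exactly.
#'
#' @param spec A [cohort_spec()]; its `scenario_id` must match
#'   `scenario`.
#' @param scenario The [trauma_scenario()] to run against.
#' @param config An [engine_config()].
#' @param stratified Pin per-action counts (default `FALSE`).
#' @return A list of [event_log()]s (students first, then doctors).
#' @export
generate_cohort <- function(spec, scenario = default_scenario(),
                            config = engine_config(), stratified = FALSE) {
  if (!inherits(spec, "cohort_spec")) {
    validation_error("generate_cohort expects a cohort_spec")
  }
  if (!inherits(scenario, "trauma_scenario") ||
      !identical(spec$scenario_id, scenario$scenario_id)) {
    validation_error(sprintf(
      "unknown scenario: spec targets '%s'", spec$scenario_id
    ))
  }
  model <- default_reference_model(resolve_catalog(scenario$catalog_id))
  set.seed(spec$seed)
  # Scripts stay one tick inside the horizon so every scheduled action is
  # applied before any lethal-bound crossing can end the session.
  horizon <- scenario$remaining_lifetime - config$tick

  logs <- list()
  for (g in c("student", "doctor")) {
    n <- if (g == "student") spec$n_student else spec$n_doctor
    profile <- spec$profiles[[g]]
    inclusions <- if (stratified) {
      stratified_inclusions(profile, model, n)
    } else {
      replicate(n, sample_inclusion(profile, model), simplify = FALSE)
    }
    for (i in seq_len(n)) {
      script <- build_script(inclusions[[i]], profile, horizon)
      logs[[length(logs) + 1L]] <- run_session(
        scenario, script, config,
        trainee_id = sprintf("%s_%02d", g, i), group = g
      )
    }
  }
  logs
}
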
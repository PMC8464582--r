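# Action catalog: the interventions a trainee can apply, each mapped to an
# ABCDE primary-survey phase with its effects on the virtual patient.

PHASES <- c("A", "B", "C", "D", "E")

#' Define an action effect
#'
#' An effect targets either a vital sign, the blood volume, or the
#' bleeding rate. `delta` is an additive change applied instantly (for
#' `blood_volume`, a fraction of normal volume, subject to the fluid
#' efficiency rule); `mult` is a persistent multiplier on the target's
#' deterioration rate (for `bleeding_rate`, on the rate itself).
#'
#' @param vital One of the seven vital-sign names, `"blood_volume"` or
#'   `"bleeding_rate"`.
#' @param delta Additive change (default 0).
#' @param mult Rate multiplier (default 1 = unchanged).
#' @return A list of class `action_effect`.
#' @export
action_effect <- function(vital, delta = 0, mult = 1) {
  targets <- c(VITAL_NAMES, "blood_volume", "bleeding_rate")
  if (!is_scalar_string(vital) || !vital %in% targets) {
    validation_error(sprintf("effect target must be one of: %s",
                             paste(targets, collapse = ", ")))
  }
  if (!is_scalar_number(delta) || !is_scalar_number(mult) || mult < 0) {
    validation_error("effect delta must be finite and mult finite and >= 0")
  }
  structure(list(vital = vital, delta = delta, mult = mult),
            class = "action_effect")
}

#' Define a catalog action
#'
#' @param action_id Short unique identifier.
#' @param label Display name.
#' @param phase Primary-survey phase, one of `"A"`..`"E"`.
#' @param effects List of [action_effect()]s.
#' @param duration Simulated minutes the action occupies (>= 0). Durations
#'   occupy the timeline but do not pause patient deterioration.
#' @param repeatable Maximum number of times the action may be applied in
#'   one session (>= 1).
#' @param prerequisites Character vector of action_ids that canonically
#'   precede this one (documentation/validation metadata; ordering is
#'   enforced by the reference grammar, not at replay time).
#' @return A list of class `action_definition`.
#' @export
action_definition <- function(action_id, label, phase, effects = list(),
                              duration = 1, repeatable = 1,
                              prerequisites = character()) {
  problems <- character()
  if (!is_scalar_string(action_id)) {
    problems <- c(problems, "action_id must be a non-empty string")
  }
  if (!is_scalar_string(label)) {
    problems <- c(problems, "label must be a non-empty string")
  }
  if (!is_scalar_string(phase) || !phase %in% PHASES) {
    problems <- c(problems, "phase must be exactly one of A, B, C, D, E")
  }
  if (!is_scalar_number(duration) || duration < 0) {
    problems <- c(problems, "duration must be >= 0 minutes")
  }
  if (!is_scalar_number(repeatable) || repeatable < 1 ||
      repeatable != trunc(repeatable)) {
    problems <- c(problems, "repeatable must be a positive integer count")
  }
  if (!all(vapply(effects, inherits, logical(1), "action_effect"))) {
    problems <- c(problems, "effects must be a list of action_effect objects")
  }
  if (length(problems)) validation_error(problems)
  structure(
    list(
      action_id = action_id, label = label, phase = phase,
      effects = effects, duration = duration,
      repeatable = as.integer(repeatable),
      prerequisites = as.character(prerequisites)
    ),
    class = "action_definition"
  )
}

#' Built-in action catalog
#'
#' The default catalog for the pelvic trauma case. It contains the nine
#' interventions tracked in cohort reports -- airway inspection,
#' oxygenation, intubation, pelvic binder placement, blood transfusion,
#' crystalloids administration, thermal blanket, hot liquids, and talking
#' to the patient (disability assessment) -- plus the auxiliary actions
#' the default reference grammar needs (airway clearing, alternative
#' oxygen-delivery routes, vascular access routes).
#'
#' Effect conventions: oxygen-delivery actions raise SpO2 and stop its
#' decline; warming actions raise temperature and stop heat loss; the
#' pelvic binder multiplies the bleeding rate by the engine's
#' `binder_bleeding_factor`; fluids add blood volume subject to the
#' uncontrolled-hemorrhage efficiency rule.
#'
#' @return Named list of [action_definition()]s (names are action_ids).
#' @export
default_action_catalog <- function() {
  acts <- list(
    action_definition(
      "airway_inspection", "Airway inspection", "A",
      duration = 1
    ),
    action_definition(
      "airway_clearing", "Airway clearing", "A",
      effects = list(action_effect("spo2", delta = 2)),
      duration = 2, prerequisites = "airway_inspection"
    ),
    action_definition(
      "intubation", "Patient intubation", "A",
      effects = list(action_effect("spo2", delta = 8, mult = 0),
                     action_effect("respiratory_rate", delta = -4, mult = 0)),
      duration = 5, prerequisites = "airway_inspection"
    ),
    action_definition(
      "oxygenation", "Patient oxygenation", "B",
      effects = list(action_effect("spo2", delta = 10, mult = 0),
                     action_effect("respiratory_rate", delta = -6, mult = 0)),
      duration = 2
    ),
    action_definition(
      "nasal_cannula", "Nasal cannula oxygen", "B",
      effects = list(action_effect("spo2", delta = 8, mult = 0),
                     action_effect("respiratory_rate", delta = -5, mult = 0)),
      duration = 1
    ),
    action_definition(
      "bag_valve_ventilation", "Bag-valve-mask ventilation", "B",
      effects = list(action_effect("spo2", delta = 10, mult = 0),
                     action_effect("respiratory_rate", delta = -6, mult = 0)),
      duration = 2
    ),
    action_definition(
      "peripheral_iv", "Peripheral IV access", "C",
      duration = 2
    ),
    action_definition(
      "central_line", "Central venous access", "C",
      duration = 5
    ),
    action_definition(
      "pelvic_binder", "Pelvic binder placement", "C",
      effects = list(action_effect("bleeding_rate", mult = 0.1)),
      duration = 3
    ),
    action_definition(
      "blood_transfusion", "Blood transfusion", "C",
      effects = list(action_effect("blood_volume", delta = 0.15)),
      duration = 10, repeatable = 3
    ),
    action_definition(
      "crystalloids", "Crystalloids administration", "C",
      effects = list(action_effect("blood_volume", delta = 0.10)),
      duration = 5, repeatable = 3
    ),
    action_definition(
      "talk_to_patient", "Talk to the patient", "D",
      duration = 1
    ),
    action_definition(
      "thermal_blanket", "Thermal blanket", "E",
      effects = list(action_effect("temperature", delta = 0.5, mult = 0)),
      duration = 2
    ),
    action_definition(
      "hot_liquids", "Hot liquids administration", "E",
      effects = list(action_effect("temperature", delta = 1.0, mult = 0)),
      duration = 3
    )
  )
  ids <- vapply(acts, `[[`, character(1), "action_id")
  stats::setNames(acts, ids)
}

#' Resolve a catalog reference
#'
#' @param catalog_id Catalog identifier; currently `"default"` is the only
#'   built-in catalog.
#' @return A named list of `action_definition`s.
#' @export
resolve_catalog <- function(catalog_id) {
  if (identical(catalog_id, "default")) {
    return(default_action_catalog())
  }
  validation_error(sprintf("unknown catalog_id '%s'", catalog_id))
}

# Catalog-wide invariants: unique ids, resolvable prerequisites.
validate_catalog <- function(catalog) {
  ids <- vapply(catalog, `[[`, character(1), "action_id")
  problems <- character()
  if (anyDuplicated(ids)) {
    problems <- c(problems, "action_ids must be unique within a catalog")
  }
  for (a in catalog) {
    missing <- setdiff(a$prerequisites, ids)
    if (length(missing)) {
      problems <- c(problems, sprintf(
        "action '%s' has unknown prerequisites: %s",
        a$action_id, paste(missing, collapse = ", ")
      ))
    }
  }
  if (length(problems)) validation_error(problems)
  invisible(catalog)
}
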
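# Scenario model: patient profile, vital-sign vector, trauma scenario,
# and their (de)serialization to trainer-editable YAML/JSON files.

# Canonical vital-sign panel monitored by the simulator. Consciousness is a
# GCS-like ordinal on 3..15.
VITAL_NAMES <- c(
  "heart_rate", "systolic_bp", "diastolic_bp", "spo2",
  "respiratory_rate", "temperature", "consciousness"
)

#' Hypothermia threshold (degrees Celsius)
#'
#' A patient is considered hypothermic when body temperature is less than
#' or equal to this value; warming measures (thermal blanket, hot liquids)
#' are indicated below it.
#' @export
HYPOTHERMIA_THRESHOLD_C <- 35.0

BODY_REGIONS <- c("head", "neck", "chest", "abdomen", "pelvis", "limb")

# Physiological clipping ranges: action effects and dynamics never push a
# vital outside these (e.g. SpO2 is capped at 100).
PHYS_RANGE <- list(
  heart_rate       = c(0, 300),
  systolic_bp      = c(0, 300),
  diastolic_bp     = c(0, 200),
  spo2             = c(0, 100),
  respiratory_rate = c(5, 80),
  temperature      = c(25, 37.5),
  consciousness    = c(3, 15)
)

#' Construct a vital-sign vector
#'
#' The seven-field monitoring panel used throughout the simulator: heart
#' rate (bpm), systolic/diastolic blood pressure (mmHg), peripheral oxygen
#' saturation (percent), respiratory rate (breaths/min), body temperature
#' (degrees C) and a GCS-like consciousness ordinal (3--15).
#'
#' @param heart_rate Heart rate, bpm.
#' @param systolic_bp Systolic blood pressure, mmHg.
#' @param diastolic_bp Diastolic blood pressure, mmHg (must be below
#'   systolic).
#' @param spo2 Oxygen saturation, percent, in \[0, 100\].
#' @param respiratory_rate Breaths per minute.
#' @param temperature Body temperature, degrees Celsius, in \[20, 45\].
#' @param consciousness Ordinal consciousness level in \[3, 15\].
#' @return A named numeric vector of class `vital_signs`.
#' @examples
#' v <- vital_signs(110, 100, 65, 93, 22, 34.5, 13)
#' is_hypothermic(v)
#' @export
vital_signs <- function(heart_rate, systolic_bp, diastolic_bp, spo2,
                        respiratory_rate, temperature, consciousness) {
  v <- c(
    heart_rate = heart_rate, systolic_bp = systolic_bp,
    diastolic_bp = diastolic_bp, spo2 = spo2,
    respiratory_rate = respiratory_rate, temperature = temperature,
    consciousness = consciousness
  )
  problems <- validate_vitals(v)
  if (length(problems)) validation_error(problems)
  structure(v, class = "vital_signs")
}

validate_vitals <- function(v) {
  problems <- character()
  if (!is.numeric(v) || length(v) != length(VITAL_NAMES) ||
      !all(VITAL_NAMES %in% names(v))) {
    return(sprintf(
      "vital signs must be numeric with fields: %s",
      paste(VITAL_NAMES, collapse = ", ")
    ))
  }
  if (any(!is.finite(v))) {
    problems <- c(problems, "all vital signs must be finite")
  } else {
    if (v[["spo2"]] < 0 || v[["spo2"]] > 100) {
      problems <- c(problems, "spo2 must lie in [0, 100]")
    }
    if (v[["diastolic_bp"]] >= v[["systolic_bp"]]) {
      problems <- c(problems, "diastolic_bp must be below systolic_bp")
    }
    if (v[["temperature"]] < 20 || v[["temperature"]] > 45) {
      problems <- c(problems, "temperature must lie in [20, 45] degrees C")
    }
    if (v[["consciousness"]] < 3 || v[["consciousness"]] > 15) {
      problems <- c(problems, "consciousness must lie in [3, 15]")
    }
  }
  problems
}

#' Hypothermia predicate
#'
#' TRUE when body temperature is at or below the 35 degrees C threshold.
#'
#' @param vitals A [vital_signs()] vector (or anything with a named
#'   `temperature` element).
#' @return Logical scalar.
#' @export
is_hypothermic <- function(vitals) {
  unname(vitals[["temperature"]] <= HYPOTHERMIA_THRESHOLD_C)
}

#' Construct a patient profile
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years, integer in \[0, 120\].
#' @param injured_region Affected body region; one of head, neck, chest,
#'   abdomen, pelvis, limb. Defaults to `"pelvis"`.
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(sex, age, injured_region = "pelvis") {
  problems <- character()
  if (!is_scalar_string(sex) || !sex %in% c("male", "female")) {
    problems <- c(problems, "sex must be 'male' or 'female'")
  }
  if (!is_scalar_number(age) || age < 0 || age > 120 || age != trunc(age)) {
    problems <- c(problems, "age must be an integer in [0, 120]")
  }
  if (!is_scalar_string(injured_region) ||
      !injured_region %in% BODY_REGIONS) {
    problems <- c(problems, sprintf(
      "injured_region must be one of: %s", paste(BODY_REGIONS, collapse = ", ")
    ))
  }
  if (length(problems)) validation_error(problems)
  structure(
    list(sex = sex, age = as.integer(age), injured_region = injured_region),
    class = "patient_profile"
  )
}

#' Default lethal bounds
#'
#' Per-vital intervals outside of which (boundary included) the virtual
#' patient dies. SpO2 has no upper lethal bound.
#'
#' @return Named list of `c(lower, upper)` pairs, one per vital.
#' @export
default_lethal_bounds <- function() {
  list(
    heart_rate       = c(20, 220),
    systolic_bp      = c(60, 260),
    diastolic_bp     = c(25, 160),
    spo2             = c(70, Inf),
    respiratory_rate = c(4, 40),
    temperature      = c(30, 41),
    consciousness    = c(2.5, 16)
  )
}

validate_lethal_bounds <- function(bounds) {
  problems <- character()
  if (!is.list(bounds) || !all(VITAL_NAMES %in% names(bounds))) {
    return("lethal_bounds must be a named list with one entry per vital")
  }
  for (nm in VITAL_NAMES) {
    b <- bounds[[nm]]
    if (!is.numeric(b) || length(b) != 2L || any(is.na(b)) || b[1] >= b[2]) {
      problems <- c(problems, sprintf(
        "lethal_bounds$%s must be c(lower, upper) with lower < upper", nm
      ))
    }
  }
  problems
}

# TRUE when every vital lies strictly inside its lethal interval.
vitals_inside_bounds <- function(vitals, bounds) {
  all(vapply(VITAL_NAMES, function(nm) {
    b <- bounds[[nm]]
    vitals[[nm]] > b[1] && vitals[[nm]] < b[2]
  }, logical(1)))
}

#' Construct a trauma scenario
#'
#' A scenario bundles the patient profile, the vital signs at arrival, the
#' remaining lifetime if no action is taken (simulated minutes), a
#' reference to an action catalog, and the per-vital lethal bounds. All
#' invariants are checked; violations are reported together in a single
#' validation error.
#'
#' @param scenario_id Identifier string.
#' @param profile A [patient_profile()].
#' @param initial_vitals A [vital_signs()] vector, strictly inside
#'   `lethal_bounds`.
#' @param remaining_lifetime Positive number of simulated minutes until
#'   death if untreated.
#' @param catalog_id Action-catalog reference; `"default"` resolves to
#'   [default_action_catalog()].
#' @param lethal_bounds Per-vital lethal intervals; see
#'   [default_lethal_bounds()].
#' @return An object of class `trauma_scenario`.
#' @seealso [load_scenario()], [save_scenario()], [default_scenario()]
#' @export
trauma_scenario <- function(scenario_id, profile, initial_vitals,
                            remaining_lifetime, catalog_id = "default",
                            lethal_bounds = default_lethal_bounds()) {
  problems <- character()
  if (!is_scalar_string(scenario_id)) {
    problems <- c(problems, "scenario_id must be a non-empty string")
  }
  if (!inherits(profile, "patient_profile")) {
    problems <- c(problems, "profile must be a patient_profile")
  }
  vit_problems <- validate_vitals(unclass(initial_vitals))
  problems <- c(problems, vit_problems)
  if (!is_scalar_number(remaining_lifetime) || remaining_lifetime <= 0) {
    problems <- c(problems, "remaining_lifetime must be > 0 minutes")
  }
  if (!is_scalar_string(catalog_id)) {
    problems <- c(problems, "catalog_id must be a non-empty string")
  } else if (is.null(tryCatch(resolve_catalog(catalog_id),
                              error = function(e) NULL))) {
    problems <- c(problems, sprintf("unknown catalog_id '%s'", catalog_id))
  }
  bnd_problems <- validate_lethal_bounds(lethal_bounds)
  problems <- c(problems, bnd_problems)
  if (!length(vit_problems) && !length(bnd_problems) &&
      !vitals_inside_bounds(initial_vitals, lethal_bounds)) {
    problems <- c(problems,
                  "initial_vitals must lie strictly inside lethal_bounds")
  }
  if (length(problems)) validation_error(problems)
  structure(
    list(
      schema_version = 1L,
      scenario_id = scenario_id,
      profile = profile,
      initial_vitals = structure(as.numeric(initial_vitals)[seq_along(VITAL_NAMES)],
                                 names = VITAL_NAMES, class = "vital_signs"),
      remaining_lifetime = as.numeric(remaining_lifetime),
      catalog_id = catalog_id,
      lethal_bounds = lethal_bounds[VITAL_NAMES]
    ),
    class = "trauma_scenario"
  )
}

# Fix initial_vitals name order defensively.
#' The built-in pelvic trauma scenario
#'
#' A hemodynamically unstable, mildly hypothermic, confused adult with an
#' isolated pelvic injury: HR 110, BP 100/65, SpO2 93%, RR 22, T 34.5 C,
#' consciousness 13, remaining lifetime 240 minutes if untreated.
#'
#' @return A `trauma_scenario`.
#' @export
default_scenario <- function() {
  trauma_scenario(
    scenario_id = "pelvic_trauma_default",
    profile = patient_profile(sex = "male", age = 34,
                              injured_region = "pelvis"),
    initial_vitals = vital_signs(
      heart_rate = 110, systolic_bp = 100, diastolic_bp = 65, spo2 = 93,
      respiratory_rate = 22, temperature = 34.5, consciousness = 13
    ),
    remaining_lifetime = 240,
    catalog_id = "default"
  )
}

# ---- serialization ---------------------------------------------------------

# Canonical list representation with fixed key order; the basis for
# byte-identical saves.
scenario_to_list <- function(scenario) {
  list(
    schema_version = as.integer(scenario$schema_version),
    scenario_id = scenario$scenario_id,
    profile = list(
      sex = scenario$profile$sex,
      age = as.integer(scenario$profile$age),
      injured_region = scenario$profile$injured_region
    ),
    initial_vitals = as.list(stats::setNames(
      as.numeric(scenario$initial_vitals[VITAL_NAMES]), VITAL_NAMES
    )),
    remaining_lifetime = scenario$remaining_lifetime,
    catalog_id = scenario$catalog_id,
    lethal_bounds = lapply(scenario$lethal_bounds[VITAL_NAMES], as.numeric)
  )
}

require_field <- function(x, field, where) {
  if (is.null(x[[field]])) {
    format_error(sprintf("missing field '%s' in %s", field, where))
  }
  x[[field]]
}

scenario_from_list <- function(x) {
  if (!is.list(x)) format_error("scenario document is not a mapping")
  ver <- require_field(x, "schema_version", "scenario")
  if (!is_scalar_number(ver) || ver != 1) {
    format_error(sprintf("unsupported schema_version '%s'", ver))
  }
  prof <- require_field(x, "profile", "scenario")
  viti <- require_field(x, "initial_vitals", "scenario")
  for (nm in VITAL_NAMES) require_field(viti, nm, "initial_vitals")
  for (nm in c("sex", "age", "injured_region")) {
    require_field(prof, nm, "profile")
  }
  bounds <- x[["lethal_bounds"]]
  if (is.null(bounds)) {
    bounds <- default_lethal_bounds()
  } else {
    bounds <- lapply(bounds, function(b) {
      if (is.list(b)) b[vapply(b, is.null, logical(1))] <- NA
      b <- suppressWarnings(as.numeric(unlist(b)))
      # JSON has no Inf literal; null/NA stand for an absent bound.
      if (length(b) == 2L) {
        if (is.na(b[1])) b[1] <- -Inf
        if (is.na(b[2])) b[2] <- Inf
      }
      b
    })
  }
  trauma_scenario(
    scenario_id = require_field(x, "scenario_id", "scenario"),
    profile = patient_profile(prof$sex, prof$age, prof$injured_region),
    initial_vitals = do.call(vital_signs, viti[VITAL_NAMES]),
    remaining_lifetime = require_field(x, "remaining_lifetime", "scenario"),
    catalog_id = require_field(x, "catalog_id", "scenario"),
    lethal_bounds = bounds
  )
}

#' Load a trauma scenario from file
#'
#' Reads a scenario definition from YAML (canonical) or JSON (accepted;
#' selected by a `.json` file extension) and validates it fully. Parse
#' failures raise a format error naming the offending field; invariant
#' violations raise a validation error listing every violation.
#'
#' @param path Path to a scenario file.
#' @return A validated `trauma_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  x <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                          simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) format_error(sprintf("cannot parse %s: %s", path,
                                             conditionMessage(e)))
  )
  scenario_from_list(x)
}

#' Save a trauma scenario to file
#'
#' Writes the canonical serialization (YAML, or JSON when `path` ends in
#' `.json`) with a fixed field order, so that saving the same scenario
#' twice produces byte-identical files and
#' `load_scenario(save_scenario(s))` is the identity. Scenarios that fail
#' validation are refused.
#'
#' @param scenario A `trauma_scenario`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scenario, path) {
  if (!inherits(scenario, "trauma_scenario")) {
    validation_error("save_scenario expects a trauma_scenario")
  }
  # Revalidate: an object mutated after construction must not be written.
  x <- scenario_to_list(scenario)
  revalidated <- tryCatch(scenario_from_list(x), error = function(e) e)
  if (inherits(revalidated, "error")) {
    validation_error(c("scenario no longer valid; refusing to write",
                       conditionMessage(revalidated)))
  }
  txt <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x$lethal_bounds <- lapply(x$lethal_bounds, function(b) {
      b[!is.finite(b)] <- NA  # JSON null stands for an absent bound
      b
    })
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     na = "null")
  } else {
    yaml::as.yaml(x, precision = 12L)
  }
  ok <- tryCatch({
    writeLines(txt, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write %s", path))
  invisible(path)
}

#' @export
print.trauma_scenario <- function(x, ...) {
  cat(sprintf("<trauma_scenario '%s'>\n", x$scenario_id))
  cat(sprintf("  patient: %s, %d y, injured region: %s\n",
              x$profile$sex, x$profile$age, x$profile$injured_region))
  cat(sprintf(
    "  vitals: HR %g, BP %g/%g, SpO2 %g%%, RR %g, T %g C, consciousness %g\n",
    x$initial_vitals[["heart_rate"]], x$initial_vitals[["systolic_bp"]],
    x$initial_vitals[["diastolic_bp"]], x$initial_vitals[["spo2"]],
    x$initial_vitals[["respiratory_rate"]],
    x$initial_vitals[["temperature"]], x$initial_vitals[["consciousness"]]
  ))
  cat(sprintf("  hypothermic: %s\n",
              if (is_hypothermic(x$initial_vitals)) "yes (<= 35 C)" else "no"))
  cat(sprintf("  remaining lifetime untreated: %g min; catalog: %s\n",
              x$remaining_lifetime, x$catalog_id))
  invisible(x)
}
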
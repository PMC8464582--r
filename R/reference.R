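# ATLS primary-survey reference grammar.
#
# A reference model is an ordered list of slots spanning the phases
# A -> B -> C -> D -> E. Each slot is mandatory, an alternative (choose
# exactly one of m actions), optional (0 or 1 occurrence), or repeatable
# (one base occurrence plus up to r extra repetitions). Enumerating the
# grammar yields every treatment sequence consistent with the guideline
# ordering; phases never interleave.
#
# The default model reproduces the published combinatorics of the pelvic
# case: an 8-action backbone, a x12 length-preserving multiplicity from
# three alternative slots (3 oxygen-delivery routes x 2 vascular-access
# routes x 2 warming measures), two optional airway actions giving
# (1+x)^2, and two repeatable fluid slots giving (1+x+x^2)^2 -- in total
# 12 * (1+x)^2 * (1+x+x^2)^2 = 432 sequences of lengths 8..14 with counts
# 12, 48, 96, 120, 96, 48, 12.

SLOT_TYPES <- c("mandatory", "alternative", "optional", "repeatable")

#' Define a reference-model slot
#'
#' @param type One of `"mandatory"`, `"alternative"`, `"optional"`,
#'   `"repeatable"`.
#' @param actions Character vector of action_ids: exactly one for all
#'   types except `"alternative"`, which requires at least two.
#' @param phase The ABCDE phase the slot belongs to.
#' @param max_extra For repeatable slots, the maximum number of extra
#'   repetitions beyond the base occurrence (>= 1).
#' @return A list of class `ref_slot`.
#' @export
ref_slot <- function(type, actions, phase, max_extra = 0) {
  problems <- character()
  if (!is_scalar_string(type) || !type %in% SLOT_TYPES) {
    problems <- c(problems, sprintf("slot type must be one of: %s",
                                    paste(SLOT_TYPES, collapse = ", ")))
  }
  if (!is.character(actions) || length(actions) < 1L) {
    problems <- c(problems, "actions must be a character vector of action_ids")
  } else if (identical(type, "alternative") && length(actions) < 2L) {
    problems <- c(problems, "an alternative slot needs at least two actions")
  } else if (!identical(type, "alternative") && length(actions) != 1L) {
    problems <- c(problems, sprintf("a %s slot holds exactly one action", type))
  }
  if (!is_scalar_string(phase) || !phase %in% PHASES) {
    problems <- c(problems, "phase must be one of A, B, C, D, E")
  }
  if (identical(type, "repeatable") &&
      (!is_scalar_number(max_extra) || max_extra < 1 ||
       max_extra != trunc(max_extra))) {
    problems <- c(problems, "repeatable slots need integer max_extra >= 1")
  }
  if (length(problems)) validation_error(problems)
  structure(
    list(type = type, actions = actions, phase = phase,
         max_extra = as.integer(max_extra)),
    class = "ref_slot"
  )
}

#' Construct a reference model
#'
#' Validates that every slot action exists in the catalog and that slot
#' phases follow the strict A < B < C < D < E block order (several slots
#' may share a phase, but a later slot never belongs to an earlier phase).
#'
#' @param slots List of [ref_slot()]s in guideline order.
#' @param catalog Action catalog the slots draw from.
#' @return A list of class `reference_model`.
#' @export
reference_model <- function(slots, catalog = default_action_catalog()) {
  if (!length(slots) || !all(vapply(slots, inherits, logical(1), "ref_slot"))) {
    validation_error("slots must be a non-empty list of ref_slot objects")
  }
  validate_catalog(catalog)
  known <- names(catalog)
  unknown <- setdiff(unlist(lapply(slots, `[[`, "actions")), known)
  if (length(unknown)) {
    validation_error(sprintf("slot actions not in catalog: %s",
                             paste(unknown, collapse = ", ")))
  }
  phase_idx <- match(vapply(slots, `[[`, character(1), "phase"), PHASES)
  if (is.unsorted(phase_idx)) {
    validation_error("slot phases must follow the A < B < C < D < E order")
  }
  structure(list(slots = slots, catalog = catalog), class = "reference_model")
}

#' The default pelvic-case reference model
#'
#' Encodes the guideline grammar of the built-in pelvic trauma scenario:
#' airway inspection (with optional airway clearing and intubation), one
#' oxygen-delivery route, one vascular-access route, pelvic binder, blood
#' transfusion and crystalloids (each with up to two extra repetitions), a
#' disability assessment (talking to the patient), and one warming
#' measure.
#'
#' @param catalog Catalog backing the model (default: built-in).
#' @return A `reference_model` whose enumeration has 432 sequences of
#'   lengths 8 through 14.
#' @export
default_reference_model <- function(catalog = default_action_catalog()) {
  reference_model(list(
    ref_slot("mandatory", "airway_inspection", "A"),
    ref_slot("optional", "airway_clearing", "A"),
    ref_slot("optional", "intubation", "A"),
    ref_slot("alternative",
             c("oxygenation", "nasal_cannula", "bag_valve_ventilation"), "B"),
    ref_slot("alternative", c("peripheral_iv", "central_line"), "C"),
    ref_slot("mandatory", "pelvic_binder", "C"),
    ref_slot("repeatable", "blood_transfusion", "C", max_extra = 2),
    ref_slot("repeatable", "crystalloids", "C", max_extra = 2),
    ref_slot("mandatory", "talk_to_patient", "D"),
    ref_slot("alternative", c("thermal_blanket", "hot_liquids"), "E")
  ), catalog = catalog)
}

# Expand one slot into the list of action runs it can emit.
slot_options <- function(slot) {
  switch(slot$type,
    mandatory   = list(slot$actions),
    alternative = lapply(slot$actions, identity),
    optional    = list(character(0), slot$actions),
    repeatable  = lapply(seq_len(1L + slot$max_extra), function(k) {
      rep(slot$actions, k)
    })
  )
}

#' Enumerate all reference sequences
#'
#' Expands the grammar into every distinct action sequence it generates,
#' returned duplicate-free in deterministic lexicographic order.
#'
#' @param model A [reference_model()].
#' @return A list of character vectors of action_ids.
#' @examples
#' length(enumerate_sequences(default_reference_model()))  # 432
#' @export
enumerate_sequences <- function(model) {
  if (!inherits(model, "reference_model")) {
    validation_error("enumerate_sequences expects a reference_model")
  }
  seqs <- list(character(0))
  for (slot in model$slots) {
    opts <- slot_options(slot)
    seqs <- unlist(
      lapply(seqs, function(s) lapply(opts, function(o) c(s, o))),
      recursive = FALSE
    )
  }
  keys <- vapply(seqs, paste, character(1), collapse = "\x1f")
  seqs <- seqs[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  seqs[order(keys, method = "radix")]
}

#' Histogram of reference-sequence lengths
#'
#' @param model A [reference_model()].
#' @return A named integer vector mapping sequence length to the count of
#'   reference sequences of that length (class `length_histogram`); counts
#'   sum to the total number of sequences.
#' @examples
#' length_histogram(default_reference_model())
#' @export
length_histogram <- function(model) {
  lens <- lengths(enumerate_sequences(model))
  tab <- table(lens)
  structure(stats::setNames(as.integer(tab), names(tab)),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat("Reference sequences by number of actions\n")
  for (nm in names(x)) cat(sprintf("  %2s actions: %4d sequences\n", nm, x[[nm]]))
  cat(sprintf("  total     : %4d sequences\n", sum(x)))
  invisible(x)
}

# Recursive grammar matcher with backtracking over slot options.
match_slots <- function(sequence, slots, from = 1L) {
  if (!length(slots)) return(from == length(sequence) + 1L)
  for (opt in slot_options(slots[[1L]])) {
    k <- length(opt)
    if (from + k - 1L <= length(sequence) &&
        (k == 0L || all(sequence[from:(from + k - 1L)] == opt))) {
      if (match_slots(sequence, slots[-1L], from + k)) return(TRUE)
    }
  }
  FALSE
}

#' Test whether a sequence is a valid reference sequence
#'
#' Decides membership by matching the sequence against the grammar
#' (recursive descent with backtracking), not by lookup in the enumerated
#' set; the two are equivalent by construction and cross-checked in the
#' test suite. Unknown action ids simply fail to match.
#'
#' @param sequence Character vector of action_ids.
#' @param model A [reference_model()].
#' @return Logical scalar.
#' @export
is_reference <- function(sequence, model) {
  if (!inherits(model, "reference_model")) {
    validation_error("is_reference expects a reference_model")
  }
  if (!is.character(sequence)) sequence <- as.character(sequence)
  match_slots(sequence, model$slots)
}
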
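# Shared helpers: condition classes and arithmetic conventions used across
# the package.

#' Round half away from zero
#'
#' Rounding convention used for all printed percentages: exact halves round
#' up (`round_half_up(12.5)` is 13), unlike [base::round()]'s
#' round-half-to-even. Cohort tables print integer percentages under this
#' rule, e.g. 20/28 renders as 71%.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(12.5, 13.49, 84.6))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Structured error constructors. Every malformed input surfaces as one of
# these condition classes, never as a partially constructed object.
traumasim_abort <- function(message, class) {
  stop(structure(
    class = c(class, "traumasim_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

validation_error <- function(problems) {
  traumasim_abort(
    paste(c("invalid input:", paste0("  - ", problems)), collapse = "\n"),
    "traumasim_validation_error"
  )
}

format_error <- function(message) {
  traumasim_abort(paste0("format error: ", message), "traumasim_format_error")
}

io_error <- function(message) {
  traumasim_abort(paste0("I/O error: ", message), "traumasim_io_error")
}

state_error <- function(message) {
  traumasim_abort(message, "traumasim_state_error")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}
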
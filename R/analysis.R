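# Cohort statistics: two-sample Wilcoxon rank-sum comparison (implemented
# from first principles), descriptive summaries, and Likert questionnaire
# medians.

#' Wilcoxon rank-sum test
#'
#' Compares two numeric samples on ranks. Midranks are assigned to ties.
#' When the pooled size is at most 12 and there are no ties, the p-value
#' is exact, by full enumeration of the \eqn{\binom{n_1+n_2}{n_1}} rank
#' assignments; otherwise a normal approximation with tie-corrected
#' variance and a 0.5 continuity correction is used. The test statistic is
#' the rank sum of the first sample, with null expectation
#' \eqn{n_1 (n_1+n_2+1)/2}. Significance is declared at the conventional
#' 0.05 threshold.
#'
#' A pooled sample with no variation carries no ordering evidence: the
#' p-value is reported as 1 and the result is flagged.
#'
#' @param a,b Non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   with respect to the location of `a` relative to `b`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact enumeration;
#'   `NULL` (default) picks it automatically. Exact computation is only
#'   available without ties.
#' @return A list of class `rank_sum_test`: `statistic` (rank sum of `a`),
#'   `expected`, `p_value`, `method`, `alternative`, `n1`, `n2`,
#'   `significant` (p < 0.05), `note`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p_value  # exact: 1/3
#' @export
rank_sum_test <- function(a, b,
                          alternative = c("two.sided", "less", "greater"),
                          exact = NULL) {
  alternative <- match.arg(alternative)
  if (!is.numeric(a) || !is.numeric(b) || !length(a) || !length(b)) {
    validation_error("both samples must be non-empty numeric vectors")
  }
  if (anyNA(a) || anyNA(b)) {
    validation_error("samples must not contain missing values")
  }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)                       # midranks for ties
  W <- sum(r[seq_len(n1)])
  E <- n1 * (N + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  note <- character()

  use_exact <- if (is.null(exact)) (N <= 12 && !ties) else (exact && !ties)
  if (isTRUE(exact) && ties) {
    note <- c(note, "exact computation unavailable with ties; used approximation")
  }

  if (use_exact) {
    method <- "exact"
    sums <- utils::combn(N, n1, FUN = sum)  # all rank-sum values of sample a
    eps <- 1e-9
    p <- switch(alternative,
      less      = mean(sums <= W + eps),
      greater   = mean(sums >= W - eps),
      two.sided = mean(abs(sums - E) >= abs(W - E) - eps)
    )
  } else {
    method <- "normal-approx-with-tie-correction"
    tab <- table(pooled)
    V <- n1 * n2 / 12 * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1)))
    if (V <= 0) {
      note <- c(note, "pooled sample is constant; no ordering evidence")
      p <- 1
    } else {
      s <- sqrt(V)
      p <- switch(alternative,
        less      = stats::pnorm((W - E + 0.5) / s),
        greater   = stats::pnorm((W - E - 0.5) / s, lower.tail = FALSE),
        two.sided = min(1, 2 * stats::pnorm((abs(W - E) - 0.5) / s,
                                            lower.tail = FALSE))
      )
    }
  }

  structure(
    list(statistic = W, expected = E, p_value = p, method = method,
         alternative = alternative, n1 = n1, n2 = n2,
         significant = p < 0.05,
         note = if (length(note)) paste(note, collapse = "; ") else NA_character_),
    class = "rank_sum_test"
  )
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum test (%s, %s)\n", x$method, x$alternative))
  cat(sprintf("  n1 = %d, n2 = %d, rank sum W = %g (null expectation %g)\n",
              x$n1, x$n2, x$statistic, x$expected))
  cat(sprintf("  p-value = %.4g%s\n", x$p_value,
              if (x$significant) "  (significant at 0.05)" else ""))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Descriptive summary of a numeric sample
#'
#' Mean, sample SD (n-1 denominator), median, and quartiles by linear
#' interpolation between order statistics (the convention under which
#' `{1,2,3,4}` has Q1 = 1.75 and Q3 = 3.25).
#'
#' @param sample Non-empty numeric vector without missing values.
#' @return A list with `n`, `mean`, `sd`, `median`, `q1`, `q3`.
#' @export
describe_sample <- function(sample) {
  if (!is.numeric(sample) || !length(sample)) {
    validation_error("sample must be a non-empty numeric vector")
  }
  if (anyNA(sample)) validation_error("sample must not contain missing values")
  q <- stats::quantile(sample, probs = c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  list(
    n = length(sample),
    mean = mean(sample),
    sd = if (length(sample) < 2L) 0 else stats::sd(sample),
    median = q[2L],
    q1 = q[1L],
    q3 = q[3L]
  )
}

#' The fifteen usability questionnaire items
#'
#' Closed questions on the usability of the simulator, answered on a
#' seven-point Likert scale from strongly disagree (1) to strongly
#' agree (7).
#'
#' @return Named character vector (`Q1`..`Q15`).
#' @export
likert_questions <- function() {
  c(
    Q1  = "In general, the tool is easy to use",
    Q2  = "I feel comfortable with the tool",
    Q3  = "The simulator is easy to learn",
    Q4  = "The tool shows errors and how to solve them",
    Q5  = "The information provided in the simulator is clear",
    Q6  = "It is easy to find the information",
    Q7  = "The information provided is easy to understand",
    Q8  = "The information provided is effective to support the simulation",
    Q9  = "The organization of the information in the screen is clear",
    Q10 = "Do you consider the order of the elements of the screen adequate?",
    Q11 = paste("Do you consider that all the needed parameters/monitoring",
                "information to treat a pelvic trauma scenario are shown in",
                "the simulator?"),
    Q12 = "The interface is friendly",
    Q13 = "I like the interface of the simulator",
    Q14 = paste("The simulator has all the functionalities that you would",
                "like to have in a web-based simulator"),
    Q15 = "In general, you feel satisfied with the simulator"
  )
}

#' Summarize Likert questionnaire responses
#'
#' Likert ratings are ordinal, so only medians are reported: one median
#' per question per group, plus the overall (all respondents) median per
#' question.
#'
#' @param responses A data.frame with columns `trainee_id`, `group`, and
#'   one integer column per question (`Q1`..`Q15`), each rating in 1..7.
#' @param question_ids Which questions to summarize; must be drawn from
#'   the fifteen of [likert_questions()]. Defaults to all present in
#'   `responses`.
#' @return A list of class `likert_summary` with a data.frame `medians`
#'   (`question`, `group`, `median`; the `"all"` group is the overall
#'   median).
#' @export
summarize_likert <- function(responses, question_ids = NULL) {
  if (!is.data.frame(responses) ||
      !all(c("trainee_id", "group") %in% names(responses))) {
    validation_error(
      "responses must be a data.frame with columns trainee_id, group, Q1.."
    )
  }
  known <- names(likert_questions())
  if (is.null(question_ids)) {
    question_ids <- intersect(names(responses), known)
    if (!length(question_ids)) {
      validation_error("no question columns (Q1..Q15) found in responses")
    }
  }
  unknown <- setdiff(question_ids, known)
  if (length(unknown)) {
    validation_error(sprintf("unknown question id(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  absent <- setdiff(question_ids, names(responses))
  if (length(absent)) {
    validation_error(sprintf("question column(s) missing from responses: %s",
                             paste(absent, collapse = ", ")))
  }
  for (q in question_ids) {
    v <- responses[[q]]
    if (!is.numeric(v) || anyNA(v) || any(v != trunc(v)) ||
        any(v < 1 | v > 7)) {
      validation_error(sprintf(
        "%s ratings must be integers on the 1..7 scale", q
      ))
    }
  }
  groups <- unique(as.character(responses$group))
  rows <- list()
  for (q in question_ids) {
    for (g in groups) {
      rows[[length(rows) + 1L]] <- data.frame(
        question = q, group = g,
        median = stats::median(responses[[q]][responses$group == g]),
        stringsAsFactors = FALSE
      )
    }
    rows[[length(rows) + 1L]] <- data.frame(
      question = q, group = "all", median = stats::median(responses[[q]]),
      stringsAsFactors = FALSE
    )
  }
  structure(list(medians = do.call(rbind, rows), groups = groups,
                 questions = question_ids),
            class = "likert_summary")
}

#' @export
print.likert_summary <- function(x, ...) {
  cat("Likert questionnaire medians (1-7 scale)\n")
  print(x$medians, row.names = FALSE)
  invisible(x)
}
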
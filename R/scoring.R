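# Session event logs, performance scoring against the reference grammar,
# cohort summaries, and the automatic post-session report.
#
# "Correct actions" are operationalized as the best longest-common-
# subsequence (LCS) between the session's action sequence and any
# reference sequence: the number of actions performed in the right
# relative order. "Sequential actions" are the longest contiguous block of
# the session that appears as a contiguous block of some reference
# sequence: the longest run of uninterrupted guideline adherence. Both
# reduce to the intuitive values on perfect and empty logs, and
# n_sequential <= n_correct <= n_actions always holds.

#' Construct a session event log
#'
#' @param log_id Log identifier.
#' @param scenario_id Scenario the session ran against.
#' @param trainee_id Trainee identifier.
#' @param group Cohort label, canonically `"student"` or `"doctor"`.
#' @param events Ordered list of effect records: each has `action_id`,
#'   `time` (minutes, non-decreasing), `vitals_before`, `vitals_after`.
#' @param terminal List with `outcome` (`"alive"` or `"dead"`) and
#'   `end_time` (minutes, at least the last event time).
#' @return A list of class `event_log`.
#' @export
event_log <- function(log_id, scenario_id, trainee_id, group, events,
                      terminal) {
  problems <- character()
  for (nm in c("log_id", "scenario_id", "trainee_id", "group")) {
    if (!is_scalar_string(get(nm))) {
      problems <- c(problems, sprintf("%s must be a non-empty string", nm))
    }
  }
  if (!is.list(events)) {
    problems <- c(problems, "events must be a list of event records")
    events <- list()
  }
  times <- vapply(events, function(e) as.numeric(e$time), numeric(1))
  if (length(times) && (any(!is.finite(times)) || is.unsorted(times))) {
    problems <- c(problems, "event times must be finite and non-decreasing")
  }
  if (!is.list(terminal) ||
      !is_scalar_string(terminal$outcome) ||
      !terminal$outcome %in% c("alive", "dead") ||
      !is_scalar_number(terminal$end_time)) {
    problems <- c(problems,
                  "terminal must be list(outcome = 'alive'|'dead', end_time)")
  } else if (length(times) && terminal$end_time < max(times)) {
    problems <- c(problems, "terminal end_time must be >= the last event time")
  }
  if (length(problems)) validation_error(problems)
  structure(
    list(log_id = log_id, scenario_id = scenario_id, trainee_id = trainee_id,
         group = group, events = events, terminal = terminal),
    class = "event_log"
  )
}

log_actions <- function(log) {
  vapply(log$events, `[[`, character(1), "action_id")
}

# Classic O(mn) dynamic programs, kept as plain integer-vector rows.
lcs_length <- function(a, b) {
  m <- length(a); n <- length(b)
  if (m == 0L || n == 0L) return(0L)
  prev <- integer(n + 1L)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    match_i <- a[i] == b
    for (j in seq_len(n)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[n + 1L]
}

longest_common_substring <- function(a, b) {
  m <- length(a); n <- length(b)
  if (m == 0L || n == 0L) return(0L)
  best <- 0L
  prev <- integer(n + 1L)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    match_i <- a[i] == b
    for (j in seq_len(n)) {
      if (match_i[j]) {
        cur[j + 1L] <- prev[j] + 1L
        if (cur[j + 1L] > best) best <- cur[j + 1L]
      }
    }
    prev <- cur
  }
  best
}

score_actions <- function(actions, refs) {
  if (!length(actions)) {
    return(list(n_correct = 0L, n_sequential = 0L))
  }
  n_correct <- 0L
  n_sequential <- 0L
  for (ref in refs) {
    lc <- lcs_length(actions, ref)
    if (lc > n_correct) n_correct <- lc
    ls <- longest_common_substring(actions, ref)
    if (ls > n_sequential) n_sequential <- ls
  }
  list(n_correct = n_correct, n_sequential = n_sequential)
}

#' Score a session against the reference model
#'
#' Computes the per-session performance metrics: treatment time (the
#' terminal end time), number of actions performed, number of correct
#' actions (best LCS against any reference sequence), number of
#' sequential actions (longest contiguous block shared with a reference
#' sequence), and per-action first-occurrence times. A valid log with no
#' events scores zero on all counts.
#'
#' @param log An [event_log()].
#' @param model A [reference_model()].
#' @param refs Optional pre-enumerated reference sequences (to avoid
#'   re-enumeration when scoring many logs).
#' @return A list of class `session_metrics`.
#' @export
score_session <- function(log, model = default_reference_model(),
                          refs = NULL) {
  if (!inherits(log, "event_log")) {
    validation_error("score_session expects an event_log")
  }
  if (is.null(refs)) refs <- enumerate_sequences(model)
  actions <- log_actions(log)
  sc <- score_actions(actions, refs)

  tracked <- names(model$catalog)
  first_time <- vapply(tracked, function(id) {
    hit <- which(actions == id)
    if (length(hit)) as.numeric(log$events[[hit[1L]]]$time) else NA_real_
  }, numeric(1))
  per_action <- data.frame(
    action_id = tracked,
    performed = !is.na(first_time),
    first_time = unname(first_time),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(
    list(
      log_id = log$log_id,
      treatment_time = log$terminal$end_time,
      outcome = log$terminal$outcome,
      n_actions = length(actions),
      n_correct = sc$n_correct,
      n_sequential = sc$n_sequential,
      per_action = per_action
    ),
    class = "session_metrics"
  )
}

sample_sd <- function(x) {
  if (length(x) < 2L) return(0)   # degenerate sample: SD 0 by convention
  stats::sd(x)
}

#' Cohort-level summary of session metrics
#'
#' Aggregates per-session metrics per group: mean and sample SD (n-1
#' denominator) of treatment time and the three action counts, and, per
#' catalog action, the count of sessions in which it was performed, the
#' group size, and the integer percentage (rounded half-up), formatted as
#' `"p% (k/n)"`. A derived `warming_any` row reports the union of the two
#' warming measures (thermal blanket or hot liquids). Groups with a single
#' log get SD 0 and are flagged.
#'
#' @param logs List of [event_log()]s, at least one per reported group.
#' @param model A [reference_model()].
#' @return A list of class `cohort_summary` with data.frames `numeric`
#'   (group x metric mean/sd) and `actions` (group x action k/n/pct), plus
#'   `flags`.
#' @export
cohort_metrics <- function(logs, model = default_reference_model()) {
  if (!is.list(logs) || !length(logs) ||
      !all(vapply(logs, inherits, logical(1), "event_log"))) {
    validation_error("logs must be a non-empty list of event_log objects")
  }
  refs <- enumerate_sequences(model)
  metrics <- lapply(logs, score_session, model = model, refs = refs)
  groups <- vapply(logs, `[[`, character(1), "group")
  group_levels <- unique(groups)

  numeric_names <- c("treatment_time", "n_actions", "n_correct",
                     "n_sequential")
  num_rows <- list()
  flags <- character()
  for (g in group_levels) {
    sel <- metrics[groups == g]
    if (length(sel) < 2L) {
      flags <- c(flags, sprintf(
        "group '%s' has a single session; SD reported as 0 by convention", g
      ))
    }
    for (m in numeric_names) {
      vals <- vapply(sel, `[[`, numeric(1), m)
      num_rows[[length(num_rows) + 1L]] <- data.frame(
        group = g, metric = m, n = length(vals), mean = mean(vals),
        sd = sample_sd(vals), stringsAsFactors = FALSE
      )
    }
  }
  numeric_df <- do.call(rbind, num_rows)
  numeric_df$formatted <- sprintf("%.0f ± %.0f (mean ± SD)",
                                  round_half_up(numeric_df$mean),
                                  round_half_up(numeric_df$sd))

  tracked <- c(names(model$catalog), "warming_any")
  act_rows <- list()
  for (g in group_levels) {
    sel <- metrics[groups == g]
    n <- length(sel)
    for (id in tracked) {
      k <- sum(vapply(sel, function(m) {
        pa <- m$per_action
        if (id == "warming_any") {
          any(pa$performed[pa$action_id %in% c("thermal_blanket",
                                               "hot_liquids")])
        } else {
          pa$performed[pa$action_id == id]
        }
      }, logical(1)))
      pct <- as.integer(round_half_up(100 * k / n))
      act_rows[[length(act_rows) + 1L]] <- data.frame(
        group = g, action_id = id, k = k, n = n, pct = pct,
        formatted = sprintf("%d%% (%d/%d)", pct, k, n),
        stringsAsFactors = FALSE
      )
    }
  }

  structure(
    list(numeric = numeric_df, actions = do.call(rbind, act_rows),
         n_logs = length(logs), flags = flags),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: %d sessions>\n", x$n_logs))
  cat("numeric metrics (mean ± SD):\n")
  print(x$numeric[, c("group", "metric", "mean", "sd")], row.names = FALSE)
  cat("per-action performance:\n")
  print(x$actions[, c("group", "action_id", "formatted")], row.names = FALSE)
  for (f in x$flags) cat("note:", f, "\n")
  invisible(x)
}

# ---- report generation -----------------------------------------------------

vitals_to_list <- function(v) {
  as.list(stats::setNames(as.numeric(v[VITAL_NAMES]), VITAL_NAMES))
}

report_to_list <- function(log, metrics) {
  list(
    report_version = 1L,
    log_id = log$log_id,
    scenario_id = log$scenario_id,
    trainee_id = log$trainee_id,
    group = log$group,
    terminal = list(outcome = log$terminal$outcome,
                    end_time = as.numeric(log$terminal$end_time)),
    metrics = list(
      treatment_time = as.numeric(metrics$treatment_time),
      n_actions = as.integer(metrics$n_actions),
      n_correct = as.integer(metrics$n_correct),
      n_sequential = as.integer(metrics$n_sequential),
      per_action = lapply(seq_len(nrow(metrics$per_action)), function(i) {
        row <- metrics$per_action[i, ]
        list(action_id = row$action_id, performed = row$performed,
             first_time = if (is.na(row$first_time)) NULL
                          else as.numeric(row$first_time))
      })
    ),
    events = lapply(log$events, function(e) {
      list(action_id = e$action_id, time = as.numeric(e$time),
           vitals_before = vitals_to_list(e$vitals_before),
           vitals_after = vitals_to_list(e$vitals_after))
    })
  )
}

#' Generate the automatic post-session report
#'
#' Produces the report issued at the end of a simulation: every action in
#' chronological order with the vital signs before and after it, the
#' terminal outcome, and all session metrics. Two renderings are
#' returned: canonical machine-readable JSON (re-parseable with
#' [parse_report()]) and human-readable Markdown. Content is
#' deterministic for identical inputs.
#'
#' @param log An [event_log()].
#' @param metrics The [score_session()] result for the same log; a
#'   mismatched `log_id` is an error.
#' @return A list of class `session_report` with elements `json` and
#'   `markdown` (character scalars).
#' @export
generate_report <- function(log, metrics) {
  if (!inherits(log, "event_log") || !inherits(metrics, "session_metrics")) {
    validation_error("generate_report expects an event_log and session_metrics")
  }
  if (!identical(log$log_id, metrics$log_id)) {
    validation_error(sprintf(
      "log/metrics mismatch: log_id '%s' vs '%s'", log$log_id, metrics$log_id
    ))
  }
  x <- report_to_list(log, metrics)
  json <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                        pretty = TRUE, null = "null"))

  lines <- c(
    sprintf("# Session report: %s", log$log_id),
    "",
    sprintf("- Scenario: %s", log$scenario_id),
    sprintf("- Trainee: %s (%s)", log$trainee_id, log$group),
    sprintf("- Outcome: patient %s at %g min", log$terminal$outcome,
            log$terminal$end_time),
    "",
    "## Metrics",
    "",
    sprintf("- Treatment time: %g min", metrics$treatment_time),
    sprintf("- Actions performed: %d", metrics$n_actions),
    sprintf("- Correct actions (best match to a reference sequence): %d",
            metrics$n_correct),
    sprintf("- Sequential actions (longest uninterrupted reference block): %d",
            metrics$n_sequential),
    "",
    "## Timeline",
    ""
  )
  if (length(log$events)) {
    for (e in log$events) {
      vb <- e$vitals_before; va <- e$vitals_after
      lines <- c(lines, sprintf(
        "- t=%g min: %s | BP %.0f/%.0f -> %.0f/%.0f, HR %.0f -> %.0f, SpO2 %.0f -> %.0f, T %.1f -> %.1f",
        e$time, e$action_id,
        vb[["systolic_bp"]], vb[["diastolic_bp"]],
        va[["systolic_bp"]], va[["diastolic_bp"]],
        vb[["heart_rate"]], va[["heart_rate"]],
        vb[["spo2"]], va[["spo2"]],
        vb[["temperature"]], va[["temperature"]]
      ))
    }
  } else {
    lines <- c(lines, "- (no actions were performed)")
  }
  structure(list(json = json, markdown = paste(lines, collapse = "\n")),
            class = "session_report")
}

#' Parse the machine-readable part of a session report
#'
#' @param json JSON string produced by [generate_report()].
#' @return A `session_metrics` object equal to the one the report was
#'   generated from.
#' @export
parse_report <- function(json) {
  x <- tryCatch(
    jsonlite::fromJSON(json, simplifyVector = FALSE),
    error = function(e) format_error(sprintf("cannot parse report JSON: %s",
                                             conditionMessage(e)))
  )
  m <- x$metrics
  if (is.null(m)) format_error("missing field 'metrics' in report")
  pa <- m$per_action
  per_action <- data.frame(
    action_id = vapply(pa, `[[`, character(1), "action_id"),
    performed = vapply(pa, `[[`, logical(1), "performed"),
    first_time = vapply(pa, function(p) {
      if (is.null(p$first_time)) NA_real_ else as.numeric(p$first_time)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(
      log_id = x$log_id,
      treatment_time = as.numeric(m$treatment_time),
      outcome = x$terminal$outcome,
      n_actions = as.integer(m$n_actions),
      n_correct = as.integer(m$n_correct),
      n_sequential = as.integer(m$n_sequential),
      per_action = per_action
    ),
    class = "session_metrics"
  )
}

# ---- JSONL persistence of event logs ---------------------------------------

#' Write an event log as JSONL
#'
#' One JSON record per line: a header record with the session metadata and
#' terminal event, then one record per action event.
#'
#' @param log An [event_log()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  if (!inherits(log, "event_log")) {
    validation_error("write_event_log expects an event_log")
  }
  header <- list(type = "session", log_id = log$log_id,
                 scenario_id = log$scenario_id, trainee_id = log$trainee_id,
                 group = log$group,
                 terminal = list(outcome = log$terminal$outcome,
                                 end_time = as.numeric(log$terminal$end_time)))
  recs <- c(
    list(header),
    lapply(log$events, function(e) {
      list(type = "event", action_id = e$action_id, time = as.numeric(e$time),
           vitals_before = vitals_to_list(e$vitals_before),
           vitals_after = vitals_to_list(e$vitals_after))
    })
  )
  lines <- vapply(recs, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
  }, character(1))
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write %s", path))
  invisible(path)
}

#' Read a JSONL event log
#'
#' @param path Path written by [write_event_log()].
#' @return An [event_log()].
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) format_error("empty event log file")
  recs <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l, simplifyVector = FALSE),
             error = function(e) format_error(sprintf(
               "cannot parse log line: %s", conditionMessage(e))))
  })
  header <- recs[[1L]]
  if (!identical(header$type, "session")) {
    format_error("first record must be the session header")
  }
  events <- lapply(recs[-1L], function(r) {
    if (!identical(r$type, "event")) {
      format_error("non-event record after the session header")
    }
    list(
      action_id = r$action_id, time = as.numeric(r$time),
      vitals_before = structure(
        as.numeric(unlist(r$vitals_before[VITAL_NAMES])),
        names = VITAL_NAMES),
      vitals_after = structure(
        as.numeric(unlist(r$vitals_after[VITAL_NAMES])),
        names = VITAL_NAMES)
    )
  })
  event_log(
    log_id = header$log_id, scenario_id = header$scenario_id,
    trainee_id = header$trainee_id, group = header$group,
    events = events,
    terminal = list(outcome = header$terminal$outcome,
                    end_time = as.numeric(header$terminal$end_time))
  )
}
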
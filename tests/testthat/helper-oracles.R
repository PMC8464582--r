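# Independent oracles and small fixtures used across the suite. These are
# deliberately written as brute-force enumerations, separate from the
# package's dynamic-programming / grammar code paths.

# A tiny catalog of generic actions a..f spread over the five phases, for
# toy grammars.
toy_catalog <- function() {
  ids <- letters[1:6]
  phases <- c("A", "A", "B", "C", "D", "E")
  acts <- lapply(seq_along(ids), function(i) {
    action_definition(ids[i], toupper(ids[i]), phases[i], repeatable = 5)
  })
  stats::setNames(acts, ids)
}

# Brute-force expansion of a slot list: the cartesian product of every
# slot's options, with no dedup/sort cleverness.
oracle_expand <- function(slots) {
  opts_per_slot <- lapply(slots, function(slot) {
    switch(slot$type,
      mandatory   = list(slot$actions),
      alternative = lapply(slot$actions, identity),
      optional    = list(character(0), slot$actions),
      repeatable  = lapply(seq_len(1L + slot$max_extra),
                           function(k) rep(slot$actions, k))
    )
  })
  out <- list(character(0))
  for (opts in opts_per_slot) {
    out <- unlist(lapply(out, function(s) lapply(opts, function(o) c(s, o))),
                  recursive = FALSE)
  }
  out
}

# Longest common subsequence by exhaustive enumeration of all 2^n
# subsequences of `a`, checked for subsequence membership in `b`.
oracle_lcs <- function(a, b) {
  n <- length(a)
  if (n == 0L || length(b) == 0L) return(0L)
  is_subseq <- function(s, t) {
    if (!length(s)) return(TRUE)
    j <- 1L
    for (x in t) {
      if (x == s[j]) {
        j <- j + 1L
        if (j > length(s)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    keep <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L
    if (sum(keep) > best && is_subseq(a[keep], b)) best <- sum(keep)
  }
  best
}

# Longest common contiguous block by enumerating all substrings of `a`.
oracle_substring <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(0L)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      if (len <= best || len > m) next
      block <- a[i:j]
      for (k in seq_len(m - len + 1L)) {
        if (all(b[k:(k + len - 1L)] == block)) {
          best <- len
          break
        }
      }
    }
  }
  best
}

# Permutation oracle for the rank-sum test on tie-free data: enumerate
# every split of the pooled observations and count splits at least as
# extreme, using observation values directly (not 1..N ranks).
oracle_rank_sum_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  e <- n1 * (length(pooled) + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  ws <- apply(splits, 2L, function(idx) sum(r[idx]))
  eps <- 1e-9
  switch(alternative,
    less      = mean(ws <= w_obs + eps),
    greater   = mean(ws >= w_obs - eps),
    two.sided = mean(abs(ws - e) >= abs(w_obs - e) - eps)
  )
}

# Compact scenario with a short lifetime for fast engine property tests.
quick_scenario <- function(lifetime = 60, temperature = 34.5, spo2 = 93) {
  trauma_scenario(
    scenario_id = "pelvic_trauma_default",
    profile = patient_profile("female", 40, "pelvis"),
    initial_vitals = vital_signs(110, 100, 65, spo2, 22, temperature, 13),
    remaining_lifetime = lifetime
  )
}

# A deterministic perfect session: a reference sequence applied at fixed
# spacing from t = 0.
perfect_session <- function(scenario = default_scenario(), spacing = 2,
                            ref_index = 1L) {
  model <- default_reference_model()
  ref <- enumerate_sequences(model)[[ref_index]]
  script <- data.frame(action_id = ref,
                       time = seq(0, by = spacing, length.out = length(ref)))
  run_session(scenario, script)
}

# Construct a minimal hand-built event log from an action sequence.
manual_log <- function(actions, group = "student", trainee = "t1",
                       end_time = 240) {
  v <- vital_signs(110, 100, 65, 93, 22, 34.5, 13)
  events <- lapply(seq_along(actions), function(i) {
    list(action_id = actions[i], time = as.numeric(i),
         vitals_before = v, vitals_after = v)
  })
  event_log(
    log_id = paste0("manual__", trainee), scenario_id = "pelvic_trauma_default",
    trainee_id = trainee, group = group, events = events,
    terminal = list(outcome = "alive", end_time = end_time)
  )
}
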
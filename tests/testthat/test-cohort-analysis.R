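# Rank-sum test, descriptive statistics, Likert summaries.

test_that("a tiny exact case enumerates to p = 1/3", {
  rt <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(rt$method, "exact")
  expect_equal(rt$p_value, 1 / 3)
  expect_equal(rt$statistic, 3)
  expect_false(rt$significant)
})

test_that("identical samples sit at the null expectation", {
  x <- c(3.2, 5.1, 7.7, 2.2)
  rt <- rank_sum_test(x, x)
  expect_equal(rt$statistic, rt$expected)
  expect_equal(rt$expected, length(x) * (2 * length(x) + 1) / 2)
  expect_gte(rt$p_value, 0.99)
})

test_that("exact p-values equal the permutation oracle on all tie-free
           instances with pooled size <= 10", {
  for (N in 2:10) {
    for (n1 in 1:(N - 1)) {
      subsets <- utils::combn(N, n1)
      for (col in seq_len(ncol(subsets))) {
        a_ranks <- subsets[, col]
        # map ranks to distinct values via a strictly monotone transform
        vals <- (1:N)^2 + 0.5
        a <- vals[a_ranks]
        b <- vals[-a_ranks]
        for (alt in c("two.sided", "less", "greater")) {
          expect_equal(
            rank_sum_test(a, b, alternative = alt)$p_value,
            oracle_rank_sum_p(a, b, alternative = alt)
          )
        }
      }
    }
  }
})

test_that("exact p-values match the reference implementation on samples", {
  set.seed(12)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- round(rnorm(n1), 3)
    b <- round(rnorm(n2, mean = 0.5), 3)
    if (anyDuplicated(c(a, b))) next
    rt <- rank_sum_test(a, b)
    wt <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(rt$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("the approximation tracks the exhaustive oracle at n1 = n2 = 8", {
  # Exhaustive over every achievable statistic value: realize each rank
  # sum W of sample a via the split {ranks in W} vs the rest, and compare
  # the approximate two-sided p with the 12870-split oracle. With the
  # continuity correction the worst-case absolute error over the whole
  # null distribution is 0.0109 (enumerated); typical-W error is ~0.003.
  splits <- utils::combn(16, 8)
  seen <- integer()
  errs <- numeric()
  for (col in seq_len(ncol(splits))) {
    w <- sum(splits[, col])
    if (w %in% seen) next
    seen <- c(seen, w)
    a <- as.numeric(splits[, col])
    b <- as.numeric(setdiff(1:16, splits[, col]))
    rt <- rank_sum_test(a, b)   # pooled size 16 -> approximation
    expect_equal(rt$method, "normal-approx-with-tie-correction")
    errs <- c(errs, abs(rt$p_value - oracle_rank_sum_p(a, b)))
  }
  expect_lt(max(errs), 0.011)
  expect_lt(stats::median(errs), 0.01)
})

test_that("p is invariant under strictly monotone transforms (property)", {
  set.seed(99)
  for (rep in 1:10) {
    a <- runif(sample(3:9, 1), 1, 10)
    b <- runif(sample(3:9, 1), 1, 10)
    p0 <- rank_sum_test(a, b)$p_value
    expect_equal(rank_sum_test(exp(a), exp(b))$p_value, p0)
    expect_equal(rank_sum_test(log(a), log(b))$p_value, p0)
    expect_equal(rank_sum_test(2 * a + 7, 2 * b + 7)$p_value, p0)
  }
})

test_that("swapping sample labels preserves the two-sided p and mirrors
           one-sided tails", {
  set.seed(4)
  for (rep in 1:8) {
    a <- rnorm(sample(2:8, 1))
    b <- rnorm(sample(2:8, 1), mean = 1)
    expect_equal(rank_sum_test(a, b)$p_value, rank_sum_test(b, a)$p_value)
    expect_equal(rank_sum_test(a, b, alternative = "less")$p_value,
                 rank_sum_test(b, a, alternative = "greater")$p_value)
  }
})

test_that("ties get midranks and a constant pooled sample gives p = 1", {
  rt <- rank_sum_test(c(1, 1, 2), c(1, 2, 2))
  expect_equal(rt$method, "normal-approx-with-tie-correction")
  expect_true(rt$p_value >= 0 && rt$p_value <= 1)
  const <- rank_sum_test(c(5, 5), c(5, 5, 5))
  expect_equal(const$p_value, 1)
  expect_match(const$note, "constant")
  expect_false(const$significant)
  expect_error(rank_sum_test(numeric(), c(1, 2)),
               class = "traumasim_validation_error")
})

test_that("describe_sample follows the interpolating quartile convention", {
  d <- describe_sample(c(1, 2, 3, 4))
  expect_equal(d$q1, 1.75)
  expect_equal(d$q3, 3.25)
  expect_equal(d$median, 2.5)

  const <- describe_sample(c(5, 5, 5))
  expect_equal(const$mean, 5)
  expect_equal(const$sd, 0)

  odd <- describe_sample(c(9, 1, 5))
  expect_equal(odd$median, 5)   # middle order statistic

  expect_error(describe_sample(numeric()),
               class = "traumasim_validation_error")
})

test_that("likert summaries report per-group and overall medians", {
  resp <- data.frame(
    trainee_id = paste0("t", 1:5),
    group = c("student", "student", "student", "doctor", "doctor"),
    Q1 = c(7, 7, 7, 7, 7),
    Q2 = c(6, 5, 7, 3, 4),
    stringsAsFactors = FALSE
  )
  ls <- summarize_likert(resp)
  med <- function(q, g) ls$medians$median[ls$medians$question == q &
                                          ls$medians$group == g]
  expect_equal(med("Q1", "all"), 7)
  expect_equal(med("Q2", "student"), 6)
  expect_equal(med("Q2", "doctor"), 3.5)
  expect_equal(med("Q2", "all"), 5)
  expect_true(all(ls$medians$median >= 1 & ls$medians$median <= 7))
})

test_that("likert validation rejects out-of-scale and unknown questions", {
  resp <- data.frame(trainee_id = "t1", group = "student", Q1 = 8)
  expect_error(summarize_likert(resp), class = "traumasim_validation_error")
  resp2 <- data.frame(trainee_id = "t1", group = "student", Q1 = 5)
  expect_error(summarize_likert(resp2, question_ids = "Q99"),
               class = "traumasim_validation_error")
  expect_length(likert_questions(), 15)
})
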
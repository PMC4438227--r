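test_that("trial logs enforce the correctness convention", {
  log <- log_from_outcomes(c(TRUE, TRUE, FALSE, TRUE))
  expect_s3_class(log, "trial_log")
  expect_equal(sum(log$correct), 3)
  bad <- as.data.frame(log)
  bad$correct[1] <- FALSE
  expect_error(trial_log(bad), "inconsistent")
  expect_error(trial_log(data.frame(rat_id = 1)), "lacks columns")
})

test_that("last-session performance pools trials with an exact binomial CI", {
  perfect <- performance_last_sessions(log_from_outcomes(rep(TRUE, 40)), k = 4)
  expect_equal(perfect$proportion, 1)
  expect_equal(perfect$ci_high, 1)

  half <- performance_last_sessions(
    log_from_outcomes(rep(c(TRUE, FALSE), 20)), k = 4
  )
  expect_equal(half$proportion, 0.5)
  expect_lt(half$ci_low, 0.5); expect_gt(half$ci_high, 0.5)

  # 30/40 against an independent bisection inversion of the binomial CDF
  obs <- performance_last_sessions(
    log_from_outcomes(rep(c(TRUE, TRUE, TRUE, FALSE), 10)), k = 4
  )
  expect_equal(obs$proportion, 0.75)
  invert <- function(target_tail, x, n) {
    # smallest/largest p with the stated tail probability at the observed x
    f_lo <- function(p) 1 - stats::pbinom(x - 1, n, p) - target_tail
    f_hi <- function(p) stats::pbinom(x, n, p) - target_tail
    c(stats::uniroot(f_lo, c(1e-9, 1 - 1e-9), tol = 1e-10)$root,
      stats::uniroot(f_hi, c(1e-9, 1 - 1e-9), tol = 1e-10)$root)
  }
  ci <- invert(0.025, 30, 40)
  expect_equal(obs$ci_low, ci[1], tolerance = 1e-6)
  expect_equal(obs$ci_high, ci[2], tolerance = 1e-6)

  expect_error(performance_last_sessions(log_from_outcomes(rep(TRUE, 20)), k = 4),
               "sessions")
})

test_that("the last-k window is by session index and order-invariant", {
  log <- log_from_outcomes(c(rep(FALSE, 20), rep(TRUE, 40)))  # 6 sessions
  expect_equal(performance_last_sessions(log, k = 4)$proportion, 1)
  shuffled <- log[sample(nrow(log)), ]
  class(shuffled) <- class(log)
  expect_equal(performance_last_sessions(shuffled, k = 4)$proportion, 1)
})

test_that("the pairwise permutation test matches an exact tail oracle", {
  a <- log_from_outcomes(rep(c(TRUE, FALSE), c(95, 5)))
  b <- log_from_outcomes(rep(c(TRUE, FALSE), c(55, 45)))
  res <- performance_difference_test(a, b, n_iter = 2000, seed = 5)
  expect_true(res$significant)
  expect_equal(res$difference, 0.4)
  # exact null: with 150 successes among 200 pooled trials, the count in A is
  # hypergeometric; a gap this large is essentially impossible under the null
  p_tail <- 1 - stats::phyper(94, 150, 50, 100)
  expect_lt(p_tail, 1e-6)

  same <- performance_difference_test(a, a, n_iter = 500, seed = 5)
  expect_equal(same$difference, 0)
  expect_false(same$significant)

  # symmetry: swapping the groups flips the sign but not the verdict
  swapped <- performance_difference_test(b, a, n_iter = 2000, seed = 5)
  expect_equal(swapped$difference, -res$difference)
  expect_equal(swapped$significant, res$significant)
  expect_error(performance_difference_test(a, b, n_iter = 50), "at least 100")
})

test_that("permutation test false-positive rate is near nominal under the null", {
  set.seed(17)
  hits <- 0
  n_sim <- 300
  for (i in seq_len(n_sim)) {
    a <- stats::runif(48) < 0.7
    b <- stats::runif(48) < 0.7
    if (performance_difference_test(a, b, n_iter = 400)$significant) {
      hits <- hits + 1
    }
  }
  rate <- hits / n_sim
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("performance CIs achieve nominal coverage over simulated logs", {
  set.seed(23)
  p <- 0.75
  covered <- 0
  for (i in 1:2000) {
    log <- log_from_outcomes(stats::runif(46) < p)
    perf <- performance_last_sessions(log, k = 4)
    if (perf$ci_low <= p && p <= perf$ci_high) covered <- covered + 1
  }
  expect_gte(covered / 2000, 0.93)
})

test_that("batch consistency recovers shared per-pair difficulty", {
  v <- c(0.55, 0.65, 0.75, 0.85, 0.95, 1.0)
  res <- batch_consistency(v, v)
  expect_equal(res$value, 1)
  expect_equal(res$p_perm, 0)

  # two batches drawing 48 trials per pair from shared true accuracies
  truth <- c(0.52, 0.62, 0.72, 0.82, 0.92, 0.99)
  good <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    b1 <- stats::rbinom(6, 48, truth) / 48
    b2 <- stats::rbinom(6, 48, truth) / 48
    if (stats::cor(b1, b2) > 0.7) good <- good + 1
  }
  expect_gte(good / 20, 0.9)
})

test_that("trial logs round-trip through CSV", {
  log <- log_from_outcomes(rep(c(TRUE, FALSE, TRUE), 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(log, path)
  back <- read_trial_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log))
})
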
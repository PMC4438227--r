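test_that("chi-square match follows its definition", {
  e <- c(0.7, 0.9, 0.6, 0.8, 1.0, 0.5)
  expect_equal(chi_square_match(e, e), 0)
  expect_equal(chi_square_match(c(0.6, 0.8), c(0.5, 1.0)),
               0.01 / 0.5 + 0.04 / 1.0)
  set.seed(2)
  for (i in 1:5) {
    o <- stats::runif(6); ee <- stats::runif(6, 0.5, 1)
    acc <- 0
    for (k in 1:6) acc <- acc + (o[k] - ee[k])^2 / ee[k]
    expect_equal(chi_square_match(o, ee), acc, tolerance = 1e-10)
    expect_gte(chi_square_match(o, ee), 0)
  }
  expect_error(chi_square_match(e, c(-1, e[-1])), "positive")
})

test_that("pearson match and Fisher-Z behave as closed forms", {
  e <- c(0.7, 0.9, 0.6, 0.8, 1.0, 0.5)
  expect_equal(pearson_match(e, e), 1)
  expect_equal(pearson_match(-e, e), -1)
  set.seed(3)
  o <- stats::rnorm(6); ee <- stats::rnorm(6)
  oracle <- sum((o - mean(o)) * (ee - mean(ee))) /
    sqrt(sum((o - mean(o))^2) * sum((ee - mean(ee))^2))
  expect_equal(pearson_match(o, ee), oracle, tolerance = 1e-10)
  expect_error(pearson_match(rep(1, 6), ee), "variance")

  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2)
  expect_equal(fisher_z(-0.73), -fisher_z(0.73))
  expect_error(fisher_z(1), ">= 1")
})

test_that("derangement enumeration is exhaustive and fixed-point free", {
  expect_equal(derangements(2), matrix(c(2L, 1L), 1))
  expect_equal(nrow(derangements(6)), 265L)

  # brute-force oracle for n = 4: filter all 24 permutations
  perms <- ratvision:::all_permutations(4L)
  keep <- apply(perms, 1, function(p) all(p != 1:4))
  d4 <- derangements(4)
  expect_equal(nrow(d4), sum(keep))
  expect_equal(nrow(d4), 9L)
  expect_setequal(apply(d4, 1, paste, collapse = ""),
                  apply(perms[keep, ], 1, paste, collapse = ""))

  # subfactorial recurrence D(n) = (n-1) (D(n-1) + D(n-2))
  counts <- vapply(2:8, function(n) nrow(derangements(n)), integer(1))
  for (i in 3:length(counts)) {
    n <- i + 1
    expect_equal(counts[i], (n - 1) * (counts[i - 1] + counts[i - 2]))
  }
  for (n in c(3L, 5L)) {
    d <- derangements(n)
    expect_true(all(d != matrix(seq_len(n), nrow(d), n, byrow = TRUE)))
    expect_false(anyDuplicated(apply(d, 1, paste, collapse = ",")) > 0)
  }
  expect_error(derangements(12), "capped")
})

test_that("permutation p-values are directional and exact at the extremes", {
  e <- c(0.55, 0.65, 0.75, 0.85, 0.95, 1.0)
  res <- permutation_pvalue(e, e, "chisq")
  expect_equal(res$value, 0)
  expect_equal(res$p_perm, 0)   # no derangement of distinct values ties 0
  expect_equal(res$n_null, 265L)

  res <- permutation_pvalue(0.2 + 0.7 * e, e, "pearson")
  expect_equal(res$value, 1)
  expect_equal(res$p_perm, 0)

  # a poor chi-square match should rarely be beaten into significance
  res <- permutation_pvalue(rev(e), e, "chisq")
  expect_gt(res$p_perm, 0.05)
})

test_that("transformation index contrasts the two ends of the hierarchy", {
  set.seed(9)
  beh <- c(0.98, 0.52, 0.85, 0.57, 0.95, 0.75)
  pix <- c(0.67, 0.98, 0.75, 0.98, 0.89, 0.93)
  v1 <- pix + stats::rnorm(6, 0, 0.05)   # V1 tracks pixel geometry
  to <- beh + stats::rnorm(6, 0, 0.05)   # TO tracks behavior

  same <- transformation_index(v1, v1, beh, pix, "correlation")
  expect_equal(same$H, 0)
  same_chi <- transformation_index(v1, v1, beh, pix, "chisquare")
  expect_equal(same_chi$H, 0)

  res <- transformation_index(to, v1, beh, pix, "correlation")
  expect_gt(res$H, 0)
  expect_true(res$significant)
  expect_equal(res$null_threshold,
               stats::quantile(res$null, 0.95, names = FALSE))
  res_chi <- transformation_index(to, v1, beh, pix, "chisquare")
  expect_lt(res_chi$H, 0)

  # applying one permutation consistently to all four vectors changes nothing
  p <- c(3, 1, 6, 2, 4, 5)
  rep2 <- transformation_index(to[p], v1[p], beh[p], pix[p], "correlation")
  expect_equal(rep2$H, res$H, tolerance = 1e-12)
})

test_that("derangement null p-values are unbiased but mildly anti-conservative", {
  # Restricting the null to fixed-point-free shuffles removes the
  # permutations that partially resemble the observed arrangement, so tail
  # p-values are inflated roughly twofold relative to nominal while the
  # p-value distribution stays centered. Both properties are asserted here;
  # the inflation is discussed in the methods vignette.
  set.seed(21)
  n_draws <- 400
  p_chisq <- p_pear <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    o <- stats::runif(6, 0.5, 1)
    e <- stats::runif(6, 0.5, 1)
    p_chisq[i] <- permutation_pvalue(o, e, "chisq")$p_perm
    p_pear[i] <- permutation_pvalue(o, e, "pearson")$p_perm
  }
  expect_lt(abs(mean(p_chisq) - 0.5), 0.06)
  expect_lt(abs(mean(p_pear) - 0.5), 0.06)
  expect_gt(mean(p_chisq < 0.05), 0.02)
  expect_lte(mean(p_chisq < 0.05), 0.16)
  expect_lte(mean(p_pear < 0.05), 0.16)
})
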
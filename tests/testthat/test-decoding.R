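test_that("net responses subtract baseline rate from stimulus rate", {
  counts <- array(12, c(1, 2, 3))
  base <- array(2, c(1, 2, 3))
  tab <- spike_count_table(counts, base)
  resp <- net_responses(tab)
  expect_true(all(resp$net_rates == 12 / 4 - 2 / 2))

  zero <- spike_count_table(array(0, c(2, 2, 3)), array(0, c(2, 2, 3)))
  expect_true(all(net_responses(zero)$net_rates == 0))

  set.seed(6)
  counts <- array(stats::rpois(4 * 3 * 5, 8), c(4, 3, 5))
  base <- array(stats::rpois(4 * 3 * 5, 3), c(4, 3, 5))
  tab <- spike_count_table(counts, base, stim_duration = 4,
                           baseline_duration = 2)
  got <- net_responses(tab)$net_rates
  for (u in 1:4) for (s in 1:3) for (tr in 1:5) {
    expect_equal(got[u, s, tr], counts[u, s, tr] / 4 - base[u, s, tr] / 2,
                 tolerance = 1e-10)
  }
  expect_error(spike_count_table(array(-1, c(1, 1, 1)), array(0, c(1, 1, 1))),
               "non-negative")
})

test_that("unit selection applies the responsiveness and trial-count rules", {
  # unit 1: best shape 1.9 Hz (excluded); unit 2: best 2.1 Hz (included);
  # unit 3: strong but one shape under 12 trials (excluded)
  rates <- rbind(c(1.9, 0.5), c(2.1, 0.0), c(8.0, 8.0))
  tab <- table_from_rates(rates, n_trials = 12L)
  tab$counts[3, 2, 12] <- NA
  tab$baseline_counts[3, 2, 12] <- NA
  resp <- net_responses(tab)
  expect_equal(select_units(resp), 2L)
  expect_equal(select_units(resp, min_net_hz = 1.5, min_trials = 11), c(1L, 2L, 3L))
  expect_warning(sel <- select_units(resp, min_net_hz = 100), "no units")
  expect_length(sel, 0)
})

test_that("separable conditions decode perfectly and identical ones at chance", {
  rates <- cbind(rep(10, 8), rep(4, 8))  # disjoint, noiseless
  tab <- table_from_rates(rates, n_trials = 12L)
  resp <- net_responses(tab)
  set.seed(1)
  expect_equal(pairwise_svm_accuracy(resp, c(1, 2)), 1.0)

  flat <- two_cond_table(n_units = 20, n_trials = 60, sep = 0, seed = 8)
  resp <- net_responses(flat)
  set.seed(2)
  cfg <- decoding_config(n_resample = 40, min_trials = 60,
                         train_fraction = 50 / 60)
  accs <- replicate(40, pairwise_svm_accuracy(resp, c(1, 2), cfg,
                                              units = 1:20))
  n_dec <- 40 * 20  # test decisions per condition pooled over repeats
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / n_dec))
})

test_that("decoding is invariant to a common rate offset", {
  tab <- two_cond_table(n_units = 25, n_trials = 24, sep = 1.5, seed = 4)
  resp <- net_responses(tab)
  shifted <- resp
  shifted$net_rates <- resp$net_rates + 7.3
  cfg <- decoding_config(n_resample = 25, min_trials = 24)
  a1 <- resampled_decoding(resp, cfg, units = 1:25, seed = 99)
  a2 <- resampled_decoding(shifted, cfg, units = 1:25, seed = 99)
  expect_equal(a1$accuracy, a2$accuracy, tolerance = 1e-12)
})

test_that("resampled decoding is seed-reproducible and monotone in separation", {
  tab <- two_cond_table(n_units = 30, n_trials = 24, sep = 0.8, seed = 10)
  resp <- net_responses(tab)
  cfg <- decoding_config(n_resample = 20, n_cells = 15, min_trials = 24)
  r1 <- resampled_decoding(resp, cfg, units = 1:30, seed = 7)
  r2 <- resampled_decoding(resp, cfg, units = 1:30, seed = 7)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$accuracy_matrix, r2$accuracy_matrix)
  expect_error(resampled_decoding(resp, decoding_config(n_cells = 500,
                                                        min_trials = 24)),
               "exceeds")

  seps <- c(0.2, 0.9, 2.5)
  means <- vapply(seps, function(sp) {
    t2 <- two_cond_table(n_units = 30, n_trials = 24, sep = sp, seed = 11)
    mean(resampled_decoding(net_responses(t2),
                            decoding_config(n_resample = 15, min_trials = 24),
                            units = 1:30, seed = 3)$accuracy)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("label shuffling drives accuracy to chance", {
  tab <- two_cond_table(n_units = 25, n_trials = 24, sep = 2, seed = 12)
  resp <- net_responses(tab)
  cfg <- decoding_config(n_resample = 10, n_shuffle_outer = 10,
                         min_trials = 24)
  informative <- resampled_decoding(resp, cfg, seed = 5)
  expect_gt(mean(informative$accuracy), 0.9)
  sh <- shuffled_label_threshold(resp, cfg, seed = 5)
  n_dec <- 10 * 10 * 8  # outer x inner x test decisions
  expect_lt(abs(sh$mean - 0.5), 3 * sqrt(0.25 / n_dec))
  expect_gte(sh$threshold, sh$mean)
  expect_lt(sh$threshold, mean(informative$accuracy))
})

test_that("spike-count tables round-trip through long TSV", {
  tab <- two_cond_table(n_units = 6, n_trials = 8, sep = 1, seed = 13)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spike_counts(tab, path)
  back <- read_spike_counts(path)
  expect_equal(back$counts, tab$counts, ignore_attr = TRUE)
  expect_equal(back$baseline_counts, tab$baseline_counts, ignore_attr = TRUE)
  expect_equal(back$stim_duration, tab$stim_duration)
  expect_equal(back$area, tab$area)
})
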
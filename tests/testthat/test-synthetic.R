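test_that("area geometry interpolates between pixel and behavioral geometry", {
  d_pix <- seq(0.5, 1, length.out = 15)
  d_beh <- rep(1, 15)
  expect_equal(make_area_geometry(0, d_pix, d_beh), d_pix)
  expect_equal(make_area_geometry(1, d_pix, d_beh), d_beh)
  expect_equal(make_area_geometry(0.5, d_pix, d_beh)[1], 0.75)
  expect_error(make_area_geometry(0.5, d_pix, d_beh[-1]), "mismatch")
})

test_that("platform sides follow the cyclic LRLLRLRR schedule", {
  expect_equal(ratvision:::schedule_sides(16, 0),
               strsplit("LRLLRLRRLRLLRLRR", "")[[1]])
  expect_equal(ratvision:::schedule_sides(4, 5), c("L", "R", "R", "L"))
})

test_that("behavior logs realize the configured accuracy", {
  cfg <- synthetic_study_config(learning_ramp = FALSE,
                                sessions_per_batch = c(100L, 100L),
                                trials_per_session = 10L)
  perfect <- generate_behavior_logs(rep(1, 6), cfg, seed = 1)
  expect_true(all(perfect$correct))

  log <- generate_behavior_logs(rep(0.7, 6), cfg, seed = 2)
  one <- log[log$batch == 1 & log$pair == "pair1", ]
  expect_gte(nrow(one), 1000)
  ci <- stats::binom.test(sum(one$correct), nrow(one))$conf.int
  expect_true(ci[1] <= 0.7 && 0.7 <= ci[2])
  expect_error(generate_behavior_logs(c(0.4, rep(0.8, 5)), cfg), "0.5")
})

test_that("generated logs have the study's session structure", {
  cfg <- synthetic_study_config()
  log <- generate_behavior_logs(cfg$pair_accuracies, cfg, seed = 3)
  expect_s3_class(log, "trial_log")
  expect_equal(max(log$session[log$batch == 1]), 17L)
  expect_equal(max(log$session[log$batch == 2]), 16L)
  per_session <- table(paste(log$rat_id, log$session))
  expect_true(all(per_session %in% c(10L, 12L)))
  # with the learning ramp on, late sessions beat early ones
  early <- mean(log$correct[log$session <= 2])
  late <- mean(log$correct[log$session >= 13])
  expect_gt(late, early)
})

test_that("generated populations match their Poisson moments and pass selection", {
  target <- seq(0.55, 1, length.out = 15)
  # degenerate config with known exact rates: baseline 3 Hz, visual drive
  # 6 Hz, no shape-selective gain
  exact <- synthetic_study_config(n_units = 120L, baseline_rate_sd = 0,
                                  visual_drive_sd = 0, gain = 0)
  tab0 <- generate_area_population(target, exact, area = "V1", seed = 20)
  n <- length(tab0$baseline_counts)
  se_base <- sqrt(3 / 2 / n)   # var(mean of Poisson(6)/2) = 6 / (4 n)
  expect_lt(abs(mean(tab0$baseline_counts) / 2 - 3), 4 * se_base)
  se_stim <- sqrt(9 / 4 / n)
  expect_lt(abs(mean(tab0$counts) / 4 - 9), 4 * se_stim)

  cfg <- synthetic_study_config(n_units = 80L)
  tab <- generate_area_population(target, cfg, area = "LI", seed = 14)
  expect_s3_class(tab, "spike_count_table")
  expect_equal(dim(tab$counts), c(80L, 6L, cfg$trials_per_shape))
  resp <- net_responses(tab)
  expect_gte(length(select_units(resp)) / 80, 0.8)

  tab2 <- generate_area_population(target, cfg, area = "LI", seed = 14)
  expect_identical(tab$counts, tab2$counts)

  flat <- synthetic_study_config(n_units = 40L, gain = 0)
  tflat <- generate_area_population(target, flat, area = "V1", seed = 15)
  dec <- resampled_decoding(net_responses(tflat),
                            decoding_config(n_resample = 15), seed = 16)
  expect_lt(abs(mean(dec$accuracy) - 0.5), 0.08)
})

test_that("behavioral accuracies are assigned orthogonally to pixel geometry", {
  pix6 <- c(0.67, 0.91, 0.75, 0.98, 0.86, 0.93)
  acc <- c(0.98, 0.95, 0.85, 0.75, 0.57, 0.52)
  got <- ratvision:::assign_accuracies(acc, pix6)
  expect_setequal(got, acc)
  expect_lt(abs(stats::cor(got, pix6)), 0.15)
})

test_that("a full synthetic study is reproducible and structurally complete", {
  cfg <- synthetic_study_config(n_units = 30L)
  set <- small_set_cached()
  s1 <- generate_synthetic_study(cfg, seed = 5, stimulus_set = set)
  s2 <- generate_synthetic_study(cfg, seed = 5, stimulus_set = set)
  expect_identical(s1$tables$TO$counts, s2$tables$TO$counts)
  expect_identical(s1$logs, s2$logs)
  expect_length(s1$area_targets, 5L)
  expect_equal(s1$area_targets$V1, as.numeric(s1$d_pix))
  expect_equal(s1$area_targets$TO, s1$d_beh)
  expect_equal(sort(s1$behavioral_pairs$position),
               unique(sort(s1$behavioral_pairs$position)))
  expect_true(all(s1$d_beh >= 0.5 & s1$d_beh <= 1))
  # the configured accuracies survive assignment
  expect_setequal(s1$behavioral_pairs$accuracy, cfg$pair_accuracies)
})

test_that("decoded geometry tracks the target geometry end to end", {
  set <- small_set_cached()
  cfg <- synthetic_study_config()
  study <- generate_synthetic_study(cfg, seed = 31, stimulus_set = set)
  pos <- study$behavioral_pairs$position
  resp <- net_responses(study$tables$TO)
  dec <- resampled_decoding(resp, decoding_config(n_resample = 60),
                            pairs = pair_index(6)[pos, ], seed = 32)
  expect_gt(stats::cor(dec$accuracy, study$behavioral_pairs$accuracy), 0.5)
})
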
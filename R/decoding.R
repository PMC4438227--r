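# Population decoding of shape identity from spike-count tables: baseline
# subtraction, responsiveness/trial-count inclusion, and a resampled linear
# SVM readout with shuffled-label chance estimation.

#' Construct a spike-count table
#'
#' Stimulus-window and baseline-window spike counts per unit, shape and
#' trial. Units recorded at different times may have different trial counts;
#' missing trials are `NA`.
#'
#' @param counts Integer array `units x shapes x trials` of stimulus-window
#'   spike counts.
#' @param baseline_counts Array of the same shape with counts from the
#'   baseline window preceding each presentation.
#' @param area Area label (e.g. `"V1"`, `"LM"`, `"LI"`, `"LL"`, `"TO"`,
#'   `"V1U"`, `"V1L"`).
#' @param stim_duration Stimulus window length in seconds (default 4).
#' @param baseline_duration Baseline window length in seconds (default 2).
#' @param unit_ids Optional unit identifiers.
#' @return A `spike_count_table`.
#' @export
spike_count_table <- function(counts, baseline_counts, area = "V1",
                              stim_duration = 4, baseline_duration = 2,
                              unit_ids = NULL) {
  stopifnot(length(dim(counts)) == 3L,
            identical(dim(counts), dim(baseline_counts)),
            stim_duration > 0, baseline_duration > 0)
  if (any(counts < 0, na.rm = TRUE) || any(baseline_counts < 0, na.rm = TRUE)) {
    stop("spike counts must be non-negative")
  }
  if (is.null(unit_ids)) unit_ids <- paste0(area, "_u", seq_len(dim(counts)[1]))
  shapes <- dimnames(counts)[[2]] %||% paste0("shape", seq_len(dim(counts)[2]))
  structure(
    list(counts = counts, baseline_counts = baseline_counts, area = area,
         stim_duration = stim_duration, baseline_duration = baseline_duration,
         unit_ids = unit_ids, shapes = shapes),
    class = "spike_count_table"
  )
}

#' @export
print.spike_count_table <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<spike_count_table> area %s: %d units x %d shapes x %d trials\n",
              x$area, d[1], d[2], d[3]))
  invisible(x)
}

#' Net firing-rate responses
#'
#' Per presentation, the stimulus-window firing rate (count divided by the
#' stimulus duration) minus the rate in the preceding baseline window, in Hz.
#' Negative net rates are retained.
#'
#' @param table A `spike_count_table`.
#' @return A `population_response`: list with `net_rates` (units x shapes x
#'   trials, Hz), per-unit `responsive_mask` (best-shape trial-mean net rate
#'   above 2 Hz) and `min_trials_ok` (every shape presented at least 12
#'   times), plus area metadata. The masks are recomputed by
#'   [select_units()] for other thresholds.
#' @export
net_responses <- function(table) {
  stopifnot(inherits(table, "spike_count_table"))
  if (is.null(table$baseline_counts)) stop("baseline counts missing")
  net <- table$counts / table$stim_duration -
         table$baseline_counts / table$baseline_duration
  resp <- structure(
    list(net_rates = net, area = table$area, unit_ids = table$unit_ids,
         shapes = table$shapes),
    class = "population_response"
  )
  resp$responsive_mask <- unit_mask(resp, min_net_hz = 2)$responsive
  resp$min_trials_ok <- unit_mask(resp, min_trials = 12)$enough_trials
  resp
}

unit_mask <- function(resp, min_net_hz = 2, min_trials = 12L) {
  mean_rates <- apply(resp$net_rates, c(1, 2), mean, na.rm = TRUE)
  n_trials <- apply(!is.na(resp$net_rates), c(1, 2), sum)
  list(
    responsive = apply(mean_rates, 1, max) > min_net_hz,
    enough_trials = apply(n_trials, 1, min) >= min_trials
  )
}

#' Select units for decoding
#'
#' A unit is included when its best shape evokes a trial-averaged net
#' response above `min_net_hz` (responsiveness) and every shape was presented
#' at least `min_trials` times.
#'
#' @param resp A `population_response`.
#' @param min_net_hz Responsiveness threshold in Hz (default 2).
#' @param min_trials Minimum presentations per shape (default 12).
#' @return Integer vector of included unit indices (possibly empty, with a
#'   warning).
#' @export
select_units <- function(resp, min_net_hz = 2, min_trials = 12L) {
  stopifnot(inherits(resp, "population_response"))
  m <- unit_mask(resp, min_net_hz, min_trials)
  keep <- which(m$responsive & m$enough_trials)
  if (length(keep) == 0L) warning("no units pass the inclusion criteria")
  keep
}

#' Decoding configuration
#'
#' @param penalty SVM penalty parameter C (default 0.5).
#' @param n_resample Resampling iterations for [resampled_decoding()]
#'   (default 100).
#' @param n_cells Units per subsample; defaults to all available (the
#'   standard analysis equalizes areas at the smallest area's unit count).
#' @param train_fraction Fraction of each condition's trials used for
#'   training (default 10/12, leaving two test trials at the 12-trial
#'   minimum).
#' @param n_shuffle_outer Outer label-shuffle repeats for
#'   [shuffled_label_threshold()] (default 100).
#' @param min_trials Trials per condition used after subsampling (default 12).
#' @return A `decoding_config` list.
#' @export
decoding_config <- function(penalty = 0.5, n_resample = 100L, n_cells = NULL,
                            train_fraction = 10 / 12,
                            n_shuffle_outer = 100L, min_trials = 12L) {
  stopifnot(penalty > 0, train_fraction > 0, train_fraction < 1,
            n_resample >= 1, min_trials >= 3)
  structure(
    list(penalty = penalty, n_resample = as.integer(n_resample),
         n_cells = n_cells, train_fraction = train_fraction,
         n_shuffle_outer = as.integer(n_shuffle_outer),
         min_trials = as.integer(min_trials)),
    class = "decoding_config"
  )
}

# Draw a pseudo-population response matrix for one condition: each unit's
# trials are independently permuted (units were recorded at different times,
# so across-unit trial pairing is arbitrary) and subsampled to n_use trials.
# Returns an n_use x n_units matrix.
pseudo_population <- function(net, units, shape, n_use) {
  mat <- matrix(NA_real_, n_use, length(units))
  for (k in seq_along(units)) {
    v <- net[units[k], shape, ]
    v <- v[!is.na(v)]
    mat[, k] <- sample(v)[seq_len(n_use)]
  }
  mat
}

#' Cross-validated pairwise SVM accuracy
#'
#' One train/test evaluation for one shape pair: builds pseudo-population
#' trial vectors for both conditions, makes a random stratified train/test
#' split, fits a linear maximum-margin classifier (penalty C from the
#' config), and returns the proportion of correct decisions on the held-out
#' trials. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param resp A `population_response`.
#' @param pair Length-2 vector of shape indices (or names).
#' @param cfg A [decoding_config()].
#' @param units Unit indices to use (default: all passing [select_units()]
#'   at the config's minimum trial count).
#' @param shuffle_labels Permute condition labels across the pooled trials
#'   before the split (chance estimation).
#' @return Test-set proportion correct in `[0, 1]`.
#' @export
pairwise_svm_accuracy <- function(resp, pair, cfg = decoding_config(),
                                  units = NULL, shuffle_labels = FALSE) {
  stopifnot(inherits(resp, "population_response"), length(pair) == 2L)
  if (is.character(pair)) pair <- match(pair, resp$shapes)
  if (is.null(units)) units <- select_units(resp, min_trials = cfg$min_trials)
  if (length(units) == 0L) stop("no units available for decoding")
  avail <- apply(!is.na(resp$net_rates[units, pair, , drop = FALSE]),
                 c(1, 2), sum)
  n_use <- min(cfg$min_trials, min(avail))
  n_train <- round(cfg$train_fraction * n_use)
  n_test <- n_use - n_train
  if (n_test < 2L) stop("fewer than 2 test trials per condition")

  xa <- pseudo_population(resp$net_rates, units, pair[1], n_use)
  xb <- pseudo_population(resp$net_rates, units, pair[2], n_use)
  x <- rbind(xa, xb)
  y <- factor(rep(c("a", "b"), each = n_use))
  if (shuffle_labels) y <- y[sample.int(length(y))]
  # stratified split: n_train per condition
  tr <- c(sample(which(y == "a"), n_train), sample(which(y == "b"), n_train))
  te <- setdiff(seq_along(y), tr)
  fit <- tryCatch(
    e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
               cost = cfg$penalty, scale = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # degenerate training set (e.g. identical vectors): predict first class
    pred <- factor(rep("a", length(te)), levels = levels(y))
  } else {
    pred <- stats::predict(fit, x[te, , drop = FALSE])
  }
  mean(pred == y[te])
}

#' Resampled population decoding over shape pairs
#'
#' The standard readout: on each of `n_resample` iterations a fresh subset of
#' `n_cells` units is drawn without replacement (shared across pairs within
#' an iteration) together with fresh trial subsamples, and the pairwise SVM
#' accuracy is evaluated for every requested pair. Reported accuracies are
#' means over iterations with their SEM.
#'
#' @param resp A `population_response`.
#' @param cfg A [decoding_config()]; `cfg$n_cells = NULL` uses all selected
#'   units.
#' @param pairs Data frame with columns `n`, `m` (default: all 15 pairs).
#' @param units Candidate units (default [select_units()]).
#' @param seed Optional RNG seed.
#' @param shuffle_labels Passed to [pairwise_svm_accuracy()].
#' @return A `decoding_result`: list with per-pair `accuracy`, `sem`,
#'   `n_cells`, `n_resample`, `area`, `pairs`, and the iteration matrix
#'   `accuracy_matrix`.
#' @export
resampled_decoding <- function(resp, cfg = decoding_config(), pairs = NULL,
                               units = NULL, seed = NULL,
                               shuffle_labels = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(units)) units <- select_units(resp, min_trials = cfg$min_trials)
  n_cells <- cfg$n_cells %||% length(units)
  if (n_cells > length(units)) {
    stop(sprintf("n_cells = %d exceeds the %d available units",
                 n_cells, length(units)))
  }
  if (is.null(pairs)) pairs <- pair_index(length(resp$shapes))
  acc <- matrix(NA_real_, cfg$n_resample, nrow(pairs))
  for (it in seq_len(cfg$n_resample)) {
    sub <- sample(units, n_cells)
    for (p in seq_len(nrow(pairs))) {
      acc[it, p] <- pairwise_svm_accuracy(
        resp, c(pairs$n[p], pairs$m[p]), cfg,
        units = sub, shuffle_labels = shuffle_labels
      )
    }
  }
  structure(
    list(
      accuracy = colMeans(acc),
      sem = apply(acc, 2, stats::sd) / sqrt(cfg$n_resample),
      n_cells = n_cells, n_resample = cfg$n_resample,
      area = resp$area, pairs = pairs, accuracy_matrix = acc
    ),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> area %s: %d cells, %d resamples\n",
              x$area, x$n_cells, x$n_resample))
  cat(sprintf("  mean accuracy %.3f (pairs: %s)\n", mean(x$accuracy),
              paste(sprintf("%.2f", x$accuracy), collapse = " ")))
  invisible(x)
}

#' Shuffled-label chance threshold
#'
#' Repeats the resampled decoding analysis with condition labels shuffled on
#' every outer repeat and returns the 95th percentile of the resulting mean
#' accuracies as the chance threshold (the full published grid is 100 outer
#' repeats of 100 resampling iterations).
#'
#' @param resp A `population_response`.
#' @param cfg A [decoding_config()] (`n_shuffle_outer` outer repeats of
#'   `n_resample` inner iterations).
#' @param pairs Pairs to decode (default all).
#' @param seed Optional RNG seed.
#' @return List with `threshold` (95th percentile), `mean`, and the
#'   distribution `shuffled_means`.
#' @export
shuffled_label_threshold <- function(resp, cfg = decoding_config(),
                                     pairs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  means <- vapply(seq_len(cfg$n_shuffle_outer), function(i) {
    res <- resampled_decoding(resp, cfg, pairs = pairs,
                              shuffle_labels = TRUE)
    mean(res$accuracy)
  }, numeric(1))
  list(threshold = stats::quantile(means, 0.95, names = FALSE),
       mean = mean(means), shuffled_means = means)
}

#' Read / write spike-count tables as long-format TSV
#'
#' Columns: `unit_id`, `area`, `shape`, `trial`, `stim_count`,
#' `baseline_count`; window durations travel in a JSON sidecar
#' (`<path>.json`).
#'
#' @param table A `spike_count_table` (for writing).
#' @param path TSV path.
#' @return `read_spike_counts()` returns a `spike_count_table`.
#' @export
write_spike_counts <- function(table, path) {
  d <- dim(table$counts)
  grid <- expand.grid(unit = seq_len(d[1]), shape = seq_len(d[2]),
                      trial = seq_len(d[3]))
  df <- data.frame(
    unit_id = table$unit_ids[grid$unit], area = table$area,
    shape = table$shapes[grid$shape], trial = grid$trial,
    stim_count = as.vector(table$counts),
    baseline_count = as.vector(table$baseline_counts)
  )
  df <- df[!is.na(df$stim_count), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(stim_duration = table$stim_duration,
         baseline_duration = table$baseline_duration, area = table$area),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_spike_counts
#' @export
read_spike_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  units <- unique(df$unit_id)
  shapes <- unique(df$shape)
  n_tr <- max(df$trial)
  counts <- array(NA_real_, c(length(units), length(shapes), n_tr),
                  dimnames = list(units, shapes, NULL))
  baseline <- counts
  ui <- match(df$unit_id, units); si <- match(df$shape, shapes)
  counts[cbind(ui, si, df$trial)] <- df$stim_count
  baseline[cbind(ui, si, df$trial)] <- df$baseline_count
  spike_count_table(counts, baseline, area = meta$area,
                    stim_duration = meta$stim_duration,
                    baseline_duration = meta$baseline_duration,
                    unit_ids = units)
}
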
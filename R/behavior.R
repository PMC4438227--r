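# Behavioral analysis of visual water-maze trial logs: proportion correct
# over the final training sessions with exact binomial confidence intervals,
# permutation comparison of shape pairs, and between-batch consistency.

#' Construct/validate a water-maze trial log
#'
#' A trial log is a data frame with one row per trial and columns `rat_id`,
#' `batch`, `pair` (shape-pair label), `session` (1-based index),
#' `platform_side` (`"L"`/`"R"`), `chosen_side`, and logical `correct`. A
#' trial is correct exactly when the chosen side equals the platform side;
#' this consistency is enforced here.
#'
#' @param df Data frame with the columns above (`correct` may be omitted and
#'   is then derived).
#' @return The validated data frame with class `trial_log`.
#' @export
trial_log <- function(df) {
  need <- c("rat_id", "batch", "pair", "session", "platform_side",
            "chosen_side")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trial log lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(df$platform_side %in% c("L", "R")),
            all(df$chosen_side %in% c("L", "R")))
  derived <- df$chosen_side == df$platform_side
  if (is.null(df$correct)) {
    df$correct <- derived
  } else if (!all(as.logical(df$correct) == derived)) {
    stop("correct flags inconsistent with platform/chosen sides")
  }
  df$correct <- as.logical(df$correct)
  class(df) <- c("trial_log", "data.frame")
  df
}

#' Keep only the last k sessions of a trial log
#'
#' @param log A `trial_log`.
#' @param k Number of final sessions (by session index) to retain.
#' @return A `trial_log` restricted to those sessions.
#' @export
last_sessions <- function(log, k = 4L) {
  sess <- sort(unique(log$session))
  if (length(sess) < k) {
    stop(sprintf("log has %d sessions, need at least %d", length(sess), k))
  }
  keep <- log$session %in% utils::tail(sess, k)
  out <- log[keep, , drop = FALSE]
  class(out) <- class(log)
  out
}

#' Behavioral performance over the last k sessions
#'
#' Pools all trials of the final `k` sessions and reports the proportion of
#' correct trials with an exact (Clopper-Pearson) binomial confidence
#' interval obtained by inverting the binomial tail probabilities.
#'
#' @param log A `trial_log` (single rat/pair).
#' @param k Window: number of final sessions (default 4).
#' @param conf_level Confidence level (default 0.95).
#' @return A `behavioral_performance` list: `proportion`, `n_correct`,
#'   `n_trials`, `ci_low`, `ci_high`, `window`.
#' @export
performance_last_sessions <- function(log, k = 4L, conf_level = 0.95) {
  win <- last_sessions(log, k)
  n <- nrow(win)
  x <- sum(win$correct)
  ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
  structure(
    list(proportion = x / n, n_correct = x, n_trials = n,
         ci_low = ci[1], ci_high = ci[2], window = k),
    class = "behavioral_performance"
  )
}

#' @export
print.behavioral_performance <- function(x, ...) {
  cat(sprintf("<behavioral_performance> %.3f (%d/%d), 95%% CI [%.3f, %.3f], last %d sessions\n",
              x$proportion, x$n_correct, x$n_trials, x$ci_low, x$ci_high,
              x$window))
  invisible(x)
}

#' Permutation test for a difference in proportion correct
#'
#' Pools the correct/incorrect outcomes of the two logs, repeatedly shuffles
#' which outcomes belong to which log (preserving group sizes), and records
#' the difference in proportion correct on each iteration. The observed
#' difference is declared significant when it falls outside the central 95%
#' percentile interval of this null distribution.
#'
#' @param log_a,log_b `trial_log`s (or logical outcome vectors). Callers
#'   normally pass the last-sessions window used for performance scoring.
#' @param n_iter Number of shuffles (default 10000; must be >= 100).
#' @param seed Optional RNG seed.
#' @return List with `difference` (a minus b), `null_interval`,
#'   `significant`, `n_iter`.
#' @export
performance_difference_test <- function(log_a, log_b, n_iter = 10000L,
                                        seed = NULL) {
  if (n_iter < 100L) stop("n_iter must be at least 100")
  oa <- if (is.data.frame(log_a)) as.logical(log_a$correct) else as.logical(log_a)
  ob <- if (is.data.frame(log_b)) as.logical(log_b$correct) else as.logical(log_b)
  if (length(oa) == 0L || length(ob) == 0L) stop("empty trial log")
  if (!is.null(seed)) set.seed(seed)
  pooled <- c(oa, ob)
  na <- length(oa)
  obs <- mean(oa) - mean(ob)
  diffs <- vapply(seq_len(n_iter), function(i) {
    idx <- sample.int(length(pooled), na)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1))
  ci <- stats::quantile(diffs, c(0.025, 0.975), names = FALSE)
  list(difference = obs, null_interval = ci,
       significant = obs < ci[1] || obs > ci[2], n_iter = n_iter)
}

#' Between-batch consistency of per-pair performance
#'
#' Pearson correlation of the six per-pair performance values across the two
#' batches of animals, with a derangement permutation p-value.
#'
#' @param perf_batch1,perf_batch2 Aligned numeric vectors (one value per
#'   shape pair).
#' @return A `correspondence_result` (statistic `"pearson"`).
#' @export
batch_consistency <- function(perf_batch1, perf_batch2) {
  permutation_pvalue(perf_batch1, perf_batch2, statistic = "pearson")
}

#' Read / write trial logs as CSV
#'
#' @param path CSV path.
#' @return `read_trial_log()` returns a validated `trial_log`.
#' @export
read_trial_log <- function(path) {
  trial_log(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trial_log
#' @param log A `trial_log` to write.
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}
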
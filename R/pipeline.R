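# Full-study orchestration: stimuli -> physical dissimilarity -> per-area
# decoding -> correspondence statistics -> report.

#' Default study configuration
#'
#' One nested list drives the whole pipeline; analysis defaults are the
#' standard values used throughout the package (SVM penalty C = 0.5, 100
#' resampling iterations, 10000 behavioral permutation iterations, blur FWHM
#' 20 px). `physical$measure` selects the reference dissimilarity:
#' `"pix"` (default), `"v1sim"`, or `"average"` (mean of both rescaled
#' vectors, which are highly correlated).
#'
#' @param ... Named overrides, merged recursively into the defaults (e.g.
#'   `decoding = list(n_resample = 20)`).
#' @return Nested configuration list.
#' @export
study_config <- function(...) {
  defaults <- list(
    seed = 1L,
    synthetic = list(),   # overrides for synthetic_study_config()
    physical = list(measure = "pix", fwhm = 20),
    decoding = list(penalty = 0.5, n_resample = 100L, n_cells = NULL,
                    train_fraction = 10 / 12, min_trials = 12L),
    behavior = list(last_k = 4L, n_iter = 10000L)
  )
  modifyList(defaults, list(...))
}

merge_synth_config <- function(overrides) {
  do.call(synthetic_study_config, overrides)
}

#' Read a study configuration from a YAML or JSON file
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [study_config()] list with the file's values merged over the
#'   defaults.
#' @export
read_study_config <- function(path) {
  values <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
            else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(study_config, values)
}

#' Run the full study pipeline
#'
#' Executes every stage in dependency order on a synthetic study (or a
#' supplied one): stimulus rendering, physical dissimilarity, behavioral
#' scoring (last-four-session proportion correct with exact binomial CIs and
#' between-batch consistency), per-area resampled SVM decoding of the six
#' behavioral pairs at an equalized cell count, chi-square and Pearson
#' correspondence of each area's decoding profile with the physical and
#' behavioral references under derangement permutation nulls, and the
#' transformation index H in both modes.
#'
#' @param config A [study_config()] list (or named overrides passed through
#'   it).
#' @param seed Master seed; overrides `config$seed`.
#' @param study Optional pre-generated `synthetic_study` (stages then start
#'   from it).
#' @param out_dir Optional directory; the report (JSON) and per-stage CSVs
#'   are written there.
#' @return A `study_report` list: `decoding` (per-area per-pair accuracies,
#'   SEMs and means), `correspondence` (data frame of statistic values and
#'   permutation p per area x reference x statistic), `transformation`
#'   (both modes), `behavior` (per batch x pair performance, pooled
#'   accuracies, batch consistency), `physical` (reference vectors), and
#'   `provenance`.
#' @export
run_study <- function(config = study_config(), seed = NULL, study = NULL,
                      out_dir = NULL) {
  if (!is.null(config$seed) && is.null(seed)) seed <- config$seed
  seed <- as.integer(seed %||% 1L)
  scfg <- merge_synth_config(config$synthetic %||% list())
  if (is.null(study)) study <- generate_synthetic_study(scfg, seed = seed)

  # --- physical reference ---------------------------------------------------
  d_pix <- study$d_pix
  measure <- config$physical$measure %||% "pix"
  phys15 <- switch(measure,
    pix = as.numeric(d_pix),
    v1sim = as.numeric(v1sim_dissimilarity(study$stimulus_set,
                                           fwhm = config$physical$fwhm %||% 20)),
    average = {
      v1 <- v1sim_dissimilarity(study$stimulus_set,
                                fwhm = config$physical$fwhm %||% 20)
      (as.numeric(d_pix) + as.numeric(v1)) / 2
    },
    stop("unknown physical measure: ", measure)
  )
  pos <- study$behavioral_pairs$position
  phys6 <- phys15[pos]

  # --- behavior -------------------------------------------------------------
  last_k <- config$behavior$last_k %||% 4L
  pair_labels <- study$behavioral_pairs$label
  perf <- list()
  for (b in unique(study$logs$batch)) {
    for (pl in pair_labels) {
      sub <- study$logs[study$logs$batch == b & study$logs$pair == pl, ]
      class(sub) <- c("trial_log", "data.frame")
      p <- performance_last_sessions(sub, k = last_k)
      perf[[length(perf) + 1L]] <- data.frame(
        batch = b, pair = pl, proportion = p$proportion,
        n_trials = p$n_trials, ci_low = p$ci_low, ci_high = p$ci_high
      )
    }
  }
  perf <- do.call(rbind, perf)
  batch_vecs <- lapply(split(perf, perf$batch), function(d) {
    d$proportion[match(pair_labels, d$pair)]
  })
  consistency <- batch_consistency(batch_vecs[[1]], batch_vecs[[2]])
  # pooled per-pair accuracy across batches (trial-weighted)
  beh6 <- vapply(pair_labels, function(pl) {
    d <- perf[perf$pair == pl, ]
    sum(d$proportion * d$n_trials) / sum(d$n_trials)
  }, numeric(1))

  # --- decoding -------------------------------------------------------------
  dcfg_in <- config$decoding %||% list()
  responses <- lapply(study$tables, net_responses)
  selected <- lapply(responses, select_units,
                     min_trials = dcfg_in$min_trials %||% 12L)
  n_cells <- dcfg_in$n_cells %||% min(vapply(selected, length, integer(1)))
  cfg <- decoding_config(
    penalty = dcfg_in$penalty %||% 0.5,
    n_resample = dcfg_in$n_resample %||% 100L,
    n_cells = n_cells,
    train_fraction = dcfg_in$train_fraction %||% (10 / 12),
    min_trials = dcfg_in$min_trials %||% 12L
  )
  pairs6 <- data.frame(n = pair_index(6L)$n[pos], m = pair_index(6L)$m[pos])
  decoding <- lapply(seq_along(responses), function(i) {
    resampled_decoding(responses[[i]], cfg, pairs = pairs6,
                       units = selected[[i]], seed = seed + i)
  })
  names(decoding) <- names(responses)
  acc_mat <- do.call(rbind, lapply(decoding, `[[`, "accuracy"))
  colnames(acc_mat) <- pair_labels

  # --- correspondence -------------------------------------------------------
  refs <- list(physical = phys6, behavior = beh6)
  corr_rows <- list()
  for (area in rownames(acc_mat)) {
    for (ref in names(refs)) {
      for (statistic in c("chisq", "pearson")) {
        r <- permutation_pvalue(acc_mat[area, ], refs[[ref]], statistic)
        corr_rows[[length(corr_rows) + 1L]] <- data.frame(
          area = area, reference = ref, statistic = statistic,
          value = r$value, p_perm = r$p_perm
        )
      }
    }
  }
  correspondence <- do.call(rbind, corr_rows)

  areas <- rownames(acc_mat)
  transformation <- list(
    correlation = transformation_index(
      acc_mat[areas[length(areas)], ], acc_mat[areas[1L], ],
      beh6, phys6, mode = "correlation"
    ),
    chisquare = transformation_index(
      acc_mat[areas[length(areas)], ], acc_mat[areas[1L], ],
      beh6, phys6, mode = "chisquare"
    )
  )

  report <- structure(
    list(
      decoding = list(
        accuracy = acc_mat,
        sem = do.call(rbind, lapply(decoding, `[[`, "sem")),
        mean_accuracy = rowMeans(acc_mat),
        n_cells = n_cells, n_resample = cfg$n_resample
      ),
      correspondence = correspondence,
      transformation = lapply(transformation, function(t) {
        t[c("mode", "H", "null_threshold", "significant")]
      }),
      behavior = list(
        per_batch = perf, pooled = stats::setNames(beh6, pair_labels),
        batch_consistency = list(r = consistency$value,
                                 p_perm = consistency$p_perm)
      ),
      physical = list(measure = measure, reference6 = phys6,
                      reference15 = phys15),
      provenance = list(
        seed = seed, package_version = as.character(utils::packageVersion("ratvision")),
        r_version = R.version.string, timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  mean decoding accuracy: %s\n",
              paste(sprintf("%s=%.1f%%", names(x$decoding$mean_accuracy),
                            100 * x$decoding$mean_accuracy), collapse = " ")))
  cat(sprintf("  H (correlation) = %.3f (threshold %.3f, significant %s)\n",
              x$transformation$correlation$H,
              x$transformation$correlation$null_threshold,
              x$transformation$correlation$significant))
  cat(sprintf("  H (chisquare)  = %.4f (threshold %.4f, significant %s)\n",
              x$transformation$chisquare$H,
              x$transformation$chisquare$null_threshold,
              x$transformation$chisquare$significant))
  cat(sprintf("  batch consistency r = %.3f (p = %.3f)\n",
              x$behavior$batch_consistency$r, x$behavior$batch_consistency$p_perm))
  invisible(x)
}

#' Write a study report to disk
#'
#' Serializes the report as JSON plus per-stage CSVs (decoding accuracies,
#' correspondence statistics, behavioral performance).
#'
#' @param report A `study_report`.
#' @param out_dir Target directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  acc <- as.data.frame(report$decoding$accuracy)
  acc <- cbind(area = rownames(acc), acc, mean = report$decoding$mean_accuracy)
  utils::write.csv(acc, file.path(out_dir, "decoding_accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correspondence,
                   file.path(out_dir, "correspondence.csv"), row.names = FALSE)
  utils::write.csv(report$behavior$per_batch,
                   file.path(out_dir, "behavior_performance.csv"),
                   row.names = FALSE)
  json <- list(
    decoding = list(
      mean_accuracy = as.list(report$decoding$mean_accuracy),
      n_cells = report$decoding$n_cells,
      n_resample = report$decoding$n_resample
    ),
    transformation = report$transformation,
    behavior = list(
      pooled = as.list(report$behavior$pooled),
      batch_consistency = report$behavior$batch_consistency
    ),
    physical = list(measure = report$physical$measure),
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
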
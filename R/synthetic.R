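# Synthetic study generator: stimulus sets, area-wise spike-count tables
# whose representational geometry interpolates between pixel space and a
# behavioral target geometry, and water-maze session logs. Lets every
# downstream statistic run end-to-end without access to recordings.

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

# all permutations of 1..n as rows (n <= 7 is plenty here)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, ] <- cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub), n - 1L))
    r <- r + nrow(sub)
  }
  out
}

# Default behavioral design: three target shapes, each paired with a similar
# and a dissimilar distractor (six of the 15 pairs). Glyph order follows
# GLYPH_IDS.
DEFAULT_BEHAVIORAL_PAIRS <- data.frame(
  a = c("square", "square", "triangle", "triangle", "plus", "diamond_in_square"),
  b = c("diamond_in_square", "lambda", "lambda", "letter_H", "letter_H", "plus"),
  stringsAsFactors = FALSE
)

#' Configuration for a synthetic study
#'
#' Defaults mirror the recorded study's structure: five areas spanning the
#' cortical hierarchy with mixing weights running from pure pixel geometry
#' (w = 0, V1-like) to pure behavioral geometry (w = 1, TO-like), 12 trials
#' per shape (the inclusion minimum), six behavioral shape pairs spanning
#' near-chance to near-perfect accuracy, and two training batches of 17 and
#' 16 sessions of 10-12 trials.
#'
#' @param area_names Area labels, ordered from bottom to top of the
#'   hierarchy.
#' @param area_weights Mixing weight w per area in `[0, 1]`:
#'   the area's target 15-pair geometry is `(1 - w) * pix + w * beh`.
#' @param n_units Units generated per area.
#' @param baseline_rate_mean,baseline_rate_sd Per-unit baseline firing rate
#'   distribution (Hz; truncated below at 0.1).
#' @param visual_drive_mean,visual_drive_sd Per-unit shape-independent
#'   stimulus-evoked rate increase (Hz; truncated at 0). This is what makes
#'   most units pass the 2 Hz responsiveness rule, as in real populations
#'   where units respond to every shape but differ only modestly between
#'   shapes.
#' @param gain Response gain (Hz) scaling the shape-selective drive.
#' @param proj_scale Scaling of the shape-coordinate projection inside the
#'   softplus nonlinearity.
#' @param trials_per_shape Presentations per shape (>= 12 so units pass the
#'   trial-count inclusion rule; the default 40 reflects a 2-3 h recording
#'   session, and the decoding stage still subsamples 12 trials per
#'   condition on every iteration).
#' @param embed_dim Dimension of the multidimensional-scaling embedding.
#' @param pair_accuracies Six asymptotic per-pair behavioral accuracies in
#'   `[0.5, 1]`.
#' @param behavioral_pairs Data frame with glyph-name columns `a`, `b`
#'   selecting the six behavioral pairs.
#' @param sessions_per_batch Training sessions for the two batches.
#' @param trials_per_session Candidate session lengths (sampled per session).
#' @param learning_ramp Logical; ramp accuracy from chance to asymptote over
#'   sessions (reaching 95% of asymptote by session 8).
#' @param seed Master seed used when none is passed to the generator.
#' @return A `synthetic_study_config` list.
#' @export
synthetic_study_config <- function(
    area_names = c("V1", "LM", "LI", "LL", "TO"),
    area_weights = c(0, 0.25, 0.5, 0.75, 1),
    n_units = 200L,
    baseline_rate_mean = 3, baseline_rate_sd = 2,
    visual_drive_mean = 6, visual_drive_sd = 2,
    gain = 1.6, proj_scale = 2,
    trials_per_shape = 40L,
    embed_dim = 5L,
    pair_accuracies = c(0.98, 0.95, 0.85, 0.75, 0.57, 0.52),
    behavioral_pairs = DEFAULT_BEHAVIORAL_PAIRS,
    sessions_per_batch = c(17L, 16L),
    trials_per_session = c(10L, 12L),
    learning_ramp = TRUE,
    seed = 1L) {
  stopifnot(length(area_weights) == length(area_names),
            all(area_weights >= 0), all(area_weights <= 1),
            trials_per_shape >= 12L,
            length(pair_accuracies) == 6L,
            all(pair_accuracies >= 0.5), all(pair_accuracies <= 1),
            nrow(behavioral_pairs) == 6L)
  structure(as.list(environment()), class = "synthetic_study_config")
}

#' Target representational geometry for one area
#'
#' Element-wise mixture `(1 - w) * d_pix + w * d_beh` over the 15 pairs, so
#' w = 0 reproduces pixel geometry exactly and w = 1 the behavioral target
#' geometry.
#'
#' @param w Mixing weight in `[0, 1]`.
#' @param d_pix,d_beh 15-element dissimilarity vectors rescaled to
#'   `[0.5, 1]`.
#' @return 15-element numeric vector.
#' @export
make_area_geometry <- function(w, d_pix, d_beh) {
  stopifnot(w >= 0, w <= 1)
  d_pix <- as.numeric(d_pix); d_beh <- as.numeric(d_beh)
  if (length(d_pix) != length(d_beh)) stop("geometry length mismatch")
  (1 - w) * d_pix + w * d_beh
}

# Assign the six configured accuracies to the six behavioral pairs so that
# the accuracy vector is as uncorrelated with pixel dissimilarity as
# possible (mirrors the empirical finding that behavioral difficulty is not
# pixel-driven). Deterministic: exhaustive over the 720 assignments.
assign_accuracies <- function(accuracies, pix6) {
  perms <- all_permutations(length(accuracies))
  rs <- apply(perms, 1, function(p) stats::cor(accuracies[p], pix6))
  accuracies[perms[which.min(abs(rs)), ]]
}

# Extend the six behavioral accuracies to a full 15-pair geometry by
# interpolating accuracy against pixel dissimilarity at the known pairs.
extend_behavioral_geometry <- function(beh6, pix6, pix15, beh_positions) {
  ord <- order(pix6)
  full <- stats::approx(pix6[ord], beh6[ord], xout = as.numeric(pix15),
                        rule = 2, ties = mean)$y
  full[beh_positions] <- beh6
  pmin(1, pmax(0.5, full))
}

#' Generate a synthetic area population
#'
#' Embeds the six shapes into `embed_dim`-dimensional coordinates by
#' classical multidimensional scaling of the target 15-pair dissimilarities.
#' Each unit projects the shape coordinates onto a random direction, passes
#' the projection through a softplus nonlinearity (rates stay positive
#' without hard rectification), and emits Poisson spike counts for the 4 s
#' stimulus window plus Poisson baseline counts for the 2 s window.
#'
#' @param target 15-element dissimilarity vector (the area's geometry).
#' @param cfg A [synthetic_study_config()].
#' @param area Area label.
#' @param seed Optional RNG seed.
#' @return A `spike_count_table`.
#' @export
generate_area_population <- function(target, cfg = synthetic_study_config(),
                                     area = "V1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target <- as.numeric(target)
  stopifnot(length(target) == 15L)
  D <- matrix(0, 6, 6)
  idx <- pair_index(6L)
  D[cbind(idx$n, idx$m)] <- target
  D <- D + t(D)
  mds <- suppressWarnings(stats::cmdscale(D, k = min(cfg$embed_dim, 5L),
                                          eig = TRUE))
  eig <- mds$eig
  neg_mass <- sum(abs(eig[eig < 0])) / sum(abs(eig))
  if (neg_mass > 0.5) {
    stop("target geometry is not embeddable (negative eigenvalue mass > 50%); ",
         "increase embed_dim or smooth the target")
  }
  X <- mds$points
  if (ncol(X) < cfg$embed_dim) {
    X <- cbind(X, matrix(0, nrow(X), cfg$embed_dim - ncol(X)))
  }
  n_units <- cfg$n_units
  n_shapes <- 6L
  n_trials <- cfg$trials_per_shape
  counts <- array(NA_real_, c(n_units, n_shapes, n_trials),
                  dimnames = list(NULL, GLYPH_IDS, NULL))
  baseline <- counts
  for (u in seq_len(n_units)) {
    b <- max(0.1, stats::rnorm(1, cfg$baseline_rate_mean, cfg$baseline_rate_sd))
    v <- max(0, stats::rnorm(1, cfg$visual_drive_mean, cfg$visual_drive_sd))
    dir <- stats::rnorm(ncol(X))
    dir <- dir / sqrt(sum(dir^2))
    drive <- cfg$gain * softplus(cfg$proj_scale * as.numeric(X %*% dir))
    rate <- b + v + drive
    counts[u, , ] <- stats::rpois(n_shapes * n_trials, rep(rate * 4, n_trials))
    baseline[u, , ] <- stats::rpois(n_shapes * n_trials, b * 2)
  }
  spike_count_table(counts, baseline, area = area,
                    stim_duration = 4, baseline_duration = 2)
}

LRLLRLRR <- c("L", "R", "L", "L", "R", "L", "R", "R")

# platform sides for one session: the 8-long pseudo-random scheme, cycled
# from a random start offset
schedule_sides <- function(n_trials, start_offset) {
  LRLLRLRR[((start_offset + seq_len(n_trials) - 1L) %% 8L) + 1L]
}

#' Generate water-maze trial logs for two batches
#'
#' One rat per shape pair per batch. Platform sides follow the cyclic
#' LRLLRLRR pseudo-random schedule from a random start offset per session.
#' Per-trial correctness is Bernoulli at the pair's asymptotic accuracy,
#' optionally scaled by a logistic learning ramp that reaches 95% of
#' asymptote by session 8 (so the last four sessions sit at asymptote).
#'
#' @param pair_accuracies Named or plain numeric vector of six asymptotic
#'   accuracies in `[0.5, 1]`.
#' @param cfg A [synthetic_study_config()] (session structure).
#' @param seed Optional RNG seed.
#' @param pair_labels Labels for the six pairs (default names of
#'   `pair_accuracies` or `pair1..pair6`).
#' @return A `trial_log` covering both batches.
#' @export
generate_behavior_logs <- function(pair_accuracies,
                                   cfg = synthetic_study_config(),
                                   seed = NULL, pair_labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(pair_accuracies < 0.5) || any(pair_accuracies > 1)) {
    stop("pair accuracies must lie in [0.5, 1]")
  }
  if (is.null(pair_labels)) {
    pair_labels <- names(pair_accuracies) %||%
      paste0("pair", seq_along(pair_accuracies))
  }
  rows <- list()
  for (batch in seq_along(cfg$sessions_per_batch)) {
    n_sessions <- cfg$sessions_per_batch[batch]
    for (p in seq_along(pair_accuracies)) {
      acc <- pair_accuracies[p]
      rat <- sprintf("rat_b%d_p%d", batch, p)
      for (s in seq_len(n_sessions)) {
        n_tr <- if (length(cfg$trials_per_session) == 1L) {
          cfg$trials_per_session
        } else {
          sample(cfg$trials_per_session, 1L)
        }
        sides <- schedule_sides(n_tr, sample.int(8L, 1L) - 1L)
        ramp <- if (cfg$learning_ramp) stats::plogis((s - 4) / 1.36) else 1
        p_correct <- 0.5 + (acc - 0.5) * ramp
        ok <- stats::runif(n_tr) < p_correct
        chosen <- ifelse(ok, sides, ifelse(sides == "L", "R", "L"))
        rows[[length(rows) + 1L]] <- data.frame(
          rat_id = rat, batch = batch, pair = pair_labels[p], session = s,
          platform_side = sides, chosen_side = chosen, correct = ok,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  trial_log(do.call(rbind, rows))
}

#' Generate a complete synthetic study
#'
#' Renders (or reuses) the stimulus set, computes pixel dissimilarity,
#' assigns the configured behavioral accuracies to the six behavioral pairs
#' such that they are maximally decorrelated from pixel dissimilarity,
#' extends them to a full 15-pair behavioral geometry, generates one
#' spike-count table per area at the mixed geometry
#' `(1 - w) * pix + w * beh`, and simulates the two behavioral batches.
#'
#' @param cfg A [synthetic_study_config()].
#' @param seed Master seed (default `cfg$seed`). All randomness in the study
#'   derives from it.
#' @param stimulus_set Optional pre-built `stimulus_set` (rendering is
#'   deterministic, so reusing one across seeds is sound).
#' @return A `synthetic_study`: list with `stimulus_set`, `d_pix` (rescaled),
#'   `d_beh` (15-pair behavioral geometry), `behavioral_pairs` (with
#'   canonical positions and assigned accuracies), `area_targets`, `tables`
#'   (per-area `spike_count_table`s), `logs` (a `trial_log` for both
#'   batches), `cfg`, and `seed`.
#' @export
generate_synthetic_study <- function(cfg = synthetic_study_config(),
                                     seed = cfg$seed, stimulus_set = NULL) {
  set.seed(seed)
  if (is.null(stimulus_set)) stimulus_set <- build_stimulus_set()
  d_pix <- rescale_unit(pixel_dissimilarity(stimulus_set))
  bp <- cfg$behavioral_pairs
  ai <- match(bp$a, GLYPH_IDS); bi <- match(bp$b, GLYPH_IDS)
  pos <- pair_position(ai, bi)
  labels <- paste(pmin(ai, bi), pmax(ai, bi), sep = "-")
  pix6 <- as.numeric(d_pix)[pos]
  acc6 <- assign_accuracies(cfg$pair_accuracies, pix6)
  d_beh <- extend_behavioral_geometry(acc6, pix6, d_pix, pos)
  targets <- lapply(cfg$area_weights, make_area_geometry,
                    d_pix = as.numeric(d_pix), d_beh = d_beh)
  names(targets) <- cfg$area_names
  tables <- lapply(seq_along(cfg$area_names), function(i) {
    generate_area_population(targets[[i]], cfg, area = cfg$area_names[i])
  })
  names(tables) <- cfg$area_names
  logs <- generate_behavior_logs(acc6, cfg, pair_labels = labels)
  structure(
    list(
      stimulus_set = stimulus_set, d_pix = d_pix, d_beh = d_beh,
      behavioral_pairs = data.frame(
        a = bp$a, b = bp$b, position = pos, label = labels, accuracy = acc6,
        stringsAsFactors = FALSE
      ),
      area_targets = targets, tables = tables, logs = logs,
      cfg = cfg, seed = seed
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> seed %d: %d areas x %d units, %d behavioral pairs\n",
              x$seed, length(x$tables), x$cfg$n_units,
              nrow(x$behavioral_pairs)))
  cat("  area weights:",
      paste(sprintf("%s=%.2f", x$cfg$area_names, x$cfg$area_weights),
            collapse = " "), "\n")
  invisible(x)
}
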
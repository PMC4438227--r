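# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# full-scale default stimulus set (768 x 1280); a few seconds to build
default_set_cached <- function() memo("default_set", build_stimulus_set())

# quarter-scale set for fast tests: same glyphs and relative geometry at
# px_per_deg = 320/102
small_set_cached <- function() {
  memo("small_set", build_stimulus_set(
    specs = lapply(names(ratvision:::DEFAULT_BBOX_WIDTHS), function(g) {
      shape_spec(g, ratvision:::DEFAULT_BBOX_WIDTHS[[g]], stroke_width = 8)
    }),
    canvas_height = 192L, canvas_width = 320L, px_per_deg = 320 / 102
  ))
}

# a stimulus_set-shaped object from raw binary matrices (for exact-value
# pixel-distance tests)
set_from_rasters <- function(rasters, px_per_deg = 1) {
  shapes <- lapply(seq_along(rasters), function(i) {
    structure(list(glyph_id = paste0("g", i),
                   raster = rasters[[i]], px_per_deg = px_per_deg),
              class = "shape_image")
  })
  names(shapes) <- vapply(shapes, `[[`, character(1), "glyph_id")
  structure(
    list(shapes = shapes, pair_index = pair_index(length(shapes)),
         px_per_deg = px_per_deg,
         white_counts = vapply(rasters, sum, numeric(1))),
    class = "stimulus_set"
  )
}

# deterministic spike-count table with planted per-unit net rates:
# rates[u, s] is the exact net rate; counts are noiseless (rate * duration)
table_from_rates <- function(rates, baseline = 2, n_trials = 12L,
                             area = "TEST") {
  n_units <- nrow(rates); n_shapes <- ncol(rates)
  counts <- array(0, c(n_units, n_shapes, n_trials))
  base <- array(baseline * 2, c(n_units, n_shapes, n_trials))
  for (tr in seq_len(n_trials)) counts[, , tr] <- (rates + baseline) * 4
  spike_count_table(counts, base, area = area)
}

# small synthetic two-condition population with Gaussian-ish rate offsets
# (Poisson counts), for decoding behaviour tests
two_cond_table <- function(n_units = 30L, n_trials = 20L, sep = 0,
                           base_rate = 5, seed = 1) {
  set.seed(seed)
  pref <- stats::rnorm(n_units)
  rates <- cbind(base_rate + sep * pmax(pref, 0),
                 base_rate + sep * pmax(-pref, 0))
  counts <- array(NA_real_, c(n_units, 2L, n_trials))
  for (u in seq_len(n_units)) {
    counts[u, , ] <- stats::rpois(2L * n_trials, rep(rates[u, ] * 4, n_trials))
  }
  base <- array(stats::rpois(n_units * 2L * n_trials, base_rate * 2),
                c(n_units, 2L, n_trials))
  spike_count_table(counts, base, area = "SYN")
}

# trial log with fixed outcomes spread over sessions of 10
log_from_outcomes <- function(correct, pair = "1-2", batch = 1L,
                              rat = "rat1") {
  n <- length(correct)
  sessions <- rep(seq_len(ceiling(n / 10)), each = 10L)[seq_len(n)]
  platform <- rep(c("L", "R"), length.out = n)
  trial_log(data.frame(
    rat_id = rat, batch = batch, pair = pair, session = sessions,
    platform_side = platform,
    chosen_side = ifelse(correct, platform, ifelse(platform == "L", "R", "L")),
    stringsAsFactors = FALSE
  ))
}
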
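#' Canonical shape-pair index
#'
#' Six shapes give `choose(6, 2) = 15` unordered pairs. Every 15-element
#' dissimilarity or discriminability vector in this package is ordered by this
#' canonical index: pairs `(n, m)` with `m > n`, enumerated lexicographically
#' (1-2, 1-3, ..., 1-6, 2-3, ..., 5-6).
#'
#' @param n_shapes Number of shapes (default 6).
#' @return A data frame with integer columns `n` and `m` (`m > n`) and a
#'   `label` column `"n-m"`.
#' @examples
#' pair_index()        # 15 rows
#' pair_index(4)       # 6 rows
#' @export
pair_index <- function(n_shapes = 6L) {
  n_shapes <- as.integer(n_shapes)
  stopifnot(n_shapes >= 2L)
  cmb <- utils::combn(n_shapes, 2L)
  data.frame(
    n = cmb[1L, ],
    m = cmb[2L, ],
    label = paste(cmb[1L, ], cmb[2L, ], sep = "-")
  )
}

#' Locate pairs in the canonical index
#'
#' @param n,m Integer vectors of shape indices; order within a pair is
#'   irrelevant.
#' @param n_shapes Number of shapes in the set.
#' @return Integer positions into [pair_index()].
#' @export
pair_position <- function(n, m, n_shapes = 6L) {
  lo <- pmin(n, m)
  hi <- pmax(n, m)
  stopifnot(all(lo >= 1L), all(hi <= n_shapes), all(lo != hi))
  idx <- pair_index(n_shapes)
  match(paste(lo, hi, sep = "-"), idx$label)
}

# Dissimilarity vectors over the canonical pair index: a numeric vector with
# pair labels as names plus scale/source metadata.
new_dissimilarity <- function(values, scale = c("raw", "unit_interval"),
                              source = "other", n_shapes = 6L) {
  scale <- match.arg(scale)
  idx <- pair_index(n_shapes)
  stopifnot(length(values) == nrow(idx))
  values <- as.numeric(values)
  names(values) <- idx$label
  structure(values,
    scale = scale, source = source,
    class = c("dissimilarity_vector", "numeric")
  )
}

#' @export
print.dissimilarity_vector <- function(x, ...) {
  cat(sprintf(
    "<dissimilarity_vector> source=%s scale=%s (%d pairs)\n",
    attr(x, "source"), attr(x, "scale"), length(x)
  ))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Rescale a raw dissimilarity vector to the (0.5, 1] interval
#'
#' Divides by the maximum, halves, and adds 0.5, so the largest pairwise
#' dissimilarity maps to exactly 1 and all values lie in (0.5, 1]. The map is
#' affine and therefore preserves rank order and Pearson correlations.
#'
#' @param vec A raw `dissimilarity_vector` (or plain numeric vector).
#' @return A `dissimilarity_vector` with `scale = "unit_interval"`.
#' @export
rescale_unit <- function(vec) {
  v <- as.numeric(vec)
  mx <- max(v)
  if (!is.finite(mx) || mx <= 0) {
    stop("cannot rescale: maximum dissimilarity is not positive ",
         "(identical shapes?)")
  }
  out <- v / mx / 2 + 0.5
  structure(stats::setNames(out, names(vec)),
    scale = "unit_interval",
    source = attr(vec, "source") %||% "other",
    class = c("dissimilarity_vector", "numeric")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# smallest integer >= n whose prime factors are all in {2, 3, 5}; used to pick
# efficient FFT lengths
next_fast_size <- function(n) {
  n <- as.integer(ceiling(n))
  if (n <= 1L) return(1L)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}
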
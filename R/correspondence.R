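# Correspondence statistics between six-pair performance vectors: chi-square
# and Pearson matching with exhaustive derangement permutation nulls, and the
# transformation index H contrasting pixel-aligned and behavior-aligned
# representational geometry.

#' Chi-square match between observed and expected performance vectors
#'
#' `sum((O - E)^2 / E)`, a descriptive distance (lower = better match), not a
#' classical goodness-of-fit test. `O` is typically classifier performance
#' per shape pair; `E` a physical-dissimilarity or behavioral vector.
#'
#' @param observed,expected Numeric vectors of equal length; `expected` must
#'   be strictly positive.
#' @return The statistic (scalar, `>= 0`; 0 iff `observed == expected`).
#' @export
chi_square_match <- function(observed, expected) {
  observed <- as.numeric(observed); expected <- as.numeric(expected)
  if (length(observed) != length(expected)) stop("length mismatch")
  if (any(expected <= 0)) stop("expected values must be strictly positive")
  sum((observed - expected)^2 / expected)
}

#' Sample Pearson correlation between two performance vectors
#'
#' @param observed,expected Non-constant numeric vectors of equal length.
#' @return Pearson r.
#' @export
pearson_match <- function(observed, expected) {
  observed <- as.numeric(observed); expected <- as.numeric(expected)
  if (length(observed) != length(expected)) stop("length mismatch")
  if (stats::sd(observed) == 0 || stats::sd(expected) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(observed, expected)
}

#' Fisher-Z transformation
#'
#' `atanh(r)`; maps correlations to an approximately variance-stabilized
#' scale on which differences of correlations are contrasted.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| >= 1: Fisher-Z is unbounded")
  atanh(r)
}

#' Enumerate all derangements of n elements
#'
#' A derangement is a permutation with no fixed point: shuffles that leave
#' one or more element in its original position are excluded from the
#' permutation null. For n = 6 there are 265 derangements out of 720
#' permutations.
#'
#' @param n Number of elements (1 to 9; larger n would need sampling).
#' @return Integer matrix, one derangement per row.
#' @export
derangements <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n > 9L) stop("exhaustive enumeration capped at n = 9; sample instead")
  if (n == 1L) return(matrix(integer(0), nrow = 0L, ncol = 1L))
  # subfactorial recurrence D(n) = (n-1) * (D(n-1) + D(n-2)) for preallocation
  subf <- c(0, 1)
  for (k in seq_len(max(0L, n - 2L)) + 2L) {
    subf[k] <- (k - 1) * (subf[k - 1] + subf[k - 2])
  }
  out <- vector("list", subf[n])
  cnt <- 0L
  rec <- function(prefix, remaining) {
    pos <- length(prefix) + 1L
    if (length(remaining) == 0L) {
      cnt <<- cnt + 1L
      out[[cnt]] <<- prefix
      return(invisible(NULL))
    }
    for (v in remaining) {
      if (v != pos) rec(c(prefix, v), remaining[remaining != v])
    }
  }
  rec(integer(0), seq_len(n))
  matrix(unlist(out[seq_len(cnt)]), nrow = cnt, ncol = n, byrow = TRUE)
}

# statistic values for the observed vector permuted by every derangement,
# vectorized over rows
derangement_stats <- function(observed, expected, der,
                              statistic = c("chisq", "pearson")) {
  statistic <- match.arg(statistic)
  M <- matrix(observed[der], nrow(der), ncol(der))
  if (statistic == "chisq") {
    E <- matrix(expected, nrow(der), ncol(der), byrow = TRUE)
    rowSums((M - E)^2 / E)
  } else {
    ec <- expected - mean(expected)
    sso <- sum((observed - mean(observed))^2)
    as.numeric(M %*% ec) / sqrt(sso * sum(ec^2))
  }
}

#' Permutation p-value for a correspondence statistic
#'
#' Recomputes the statistic with the observed vector shuffled by every
#' derangement of its elements and reports the proportion of permuted values
#' strictly more extreme than the observed one. "More extreme" is
#' directional: a smaller chi-square (better match) or a larger Pearson r.
#'
#' @param observed,expected Aligned numeric vectors (length 6 in the standard
#'   analysis; any length up to 9 is supported).
#' @param statistic `"chisq"` or `"pearson"`.
#' @return A `correspondence_result`: list with `statistic`, `value`,
#'   `p_perm`, `n_null`, and the `null` distribution.
#' @export
permutation_pvalue <- function(observed, expected,
                               statistic = c("chisq", "pearson")) {
  statistic <- match.arg(statistic)
  observed <- as.numeric(observed); expected <- as.numeric(expected)
  value <- if (statistic == "chisq") chi_square_match(observed, expected)
           else pearson_match(observed, expected)
  der <- derangements(length(observed))
  null <- derangement_stats(observed, expected, der, statistic)
  extreme <- if (statistic == "chisq") sum(null < value) else sum(null > value)
  structure(
    list(statistic = statistic, value = value,
         p_perm = extreme / nrow(der), n_null = nrow(der), null = null),
    class = "correspondence_result"
  )
}

#' @export
print.correspondence_result <- function(x, ...) {
  cat(sprintf("<correspondence_result> %s = %.4f, p_perm = %.4f (%d derangements)\n",
              x$statistic, x$value, x$p_perm, x$n_null))
  invisible(x)
}

# Fisher-Z correlations of every derangement of o against fixed e
derangement_fisher_z <- function(o, e, der) {
  r <- derangement_stats(o, e, der, "pearson")
  fisher_z(r)
}

#' Transformation index H
#'
#' Contrasts how neural discriminability aligns with behavior versus pixel
#' dissimilarity at the two ends of the cortical hierarchy. In correlation
#' mode,
#' `H = [Z(TO, Beh) - Z(TO, Pix)] - [Z(V1, Beh) - Z(V1, Pix)]`
#' with Z the Fisher-transformed sample Pearson correlation; large positive H
#' indicates a shift from pixel-aligned discriminability in V1 to
#' behavior-aligned discriminability in TO. In chi-square mode the same
#' contrast is formed with the chi-square match in place of Z; the sign
#' flips, so a transformation shows up as a large *negative* index.
#'
#' The permutation null applies independent derangements to the two neural
#' vectors (behavior and pixel references stay fixed) and recomputes the
#' index for every combination. Significance is judged against the null's
#' 95th percentile (correlation mode, upper tail) or 5th percentile
#' (chi-square mode, lower tail).
#'
#' @param to_vec,v1_vec Neural discriminability for the six pairs in the top
#'   (TO) and bottom (V1) area.
#' @param beh_vec,pix_vec Behavioral performance and rescaled pixel
#'   dissimilarity for the same six pairs, in the same order.
#' @param mode `"correlation"` or `"chisquare"`.
#' @return A `transformation_index_result`: list with `mode`, `H`,
#'   `null_threshold` (95th or 5th percentile), `significant`, and the
#'   `null` distribution.
#' @export
transformation_index <- function(to_vec, v1_vec, beh_vec, pix_vec,
                                 mode = c("correlation", "chisquare")) {
  mode <- match.arg(mode)
  vecs <- lapply(list(to_vec, v1_vec, beh_vec, pix_vec), as.numeric)
  len <- unique(vapply(vecs, length, integer(1)))
  if (length(len) != 1L) stop("all four vectors must share the same pairs")
  names(vecs) <- c("to", "v1", "beh", "pix")
  der <- derangements(len)

  if (mode == "correlation") {
    term <- function(o, e) fisher_z(pearson_match(o, e))
    null_term <- function(o, e) derangement_fisher_z(o, e, der)
  } else {
    term <- function(o, e) chi_square_match(o, e)
    null_term <- function(o, e) derangement_stats(o, e, der, "chisq")
  }
  H <- (term(vecs$to, vecs$beh) - term(vecs$to, vecs$pix)) -
       (term(vecs$v1, vecs$beh) - term(vecs$v1, vecs$pix))
  # independent derangements of the two neural vectors: the null factorizes
  # into an outer difference of per-vector contrasts
  a <- null_term(vecs$to, vecs$beh) - null_term(vecs$to, vecs$pix)
  b <- null_term(vecs$v1, vecs$beh) - null_term(vecs$v1, vecs$pix)
  null <- as.numeric(outer(a, b, "-"))
  if (mode == "correlation") {
    thr <- stats::quantile(null, 0.95, names = FALSE)
    significant <- H > thr
  } else {
    thr <- stats::quantile(null, 0.05, names = FALSE)
    significant <- H < thr
  }
  structure(
    list(mode = mode, H = H, null_threshold = thr, significant = significant,
         null = null),
    class = "transformation_index_result"
  )
}

#' @export
print.transformation_index_result <- function(x, ...) {
  cat(sprintf(
    "<transformation_index> mode=%s H=%.4f threshold=%.4f significant=%s\n",
    x$mode, x$H, x$null_threshold, x$significant
  ))
  invisible(x)
}
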
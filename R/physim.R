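# Physical dissimilarity measures over the 15 shape pairs: raw pixel
# differences (PIX) and a simulated-V1 filter-bank measure (V1Sim).

#' Pixel-based dissimilarity (PIX)
#'
#' For each of the 15 pairs, the number of pixels whose binary value differs
#' between the two shape rasters (for binary images this equals the summed
#' squared difference). This is a Hamming distance: symmetric and satisfying
#' the triangle inequality.
#'
#' @param set A `stimulus_set`.
#' @return A raw `dissimilarity_vector` (source `"pix"`) over the canonical
#'   pair index.
#' @export
pixel_dissimilarity <- function(set) {
  stopifnot(inherits(set, "stimulus_set"))
  dims <- lapply(set$shapes, function(s) dim(s$raster))
  if (length(unique(dims)) != 1L) stop("shape rasters differ in size")
  idx <- set$pair_index
  vals <- vapply(seq_len(nrow(idx)), function(k) {
    a <- set$shapes[[idx$n[k]]]$raster
    b <- set$shapes[[idx$m[k]]]$raster
    sum(a != b)
  }, numeric(1))
  new_dissimilarity(vals, scale = "raw", source = "pix",
                    n_shapes = length(set$shapes))
}

# --- Gaussian preprocessing -------------------------------------------------

#' Gaussian low-pass filter an image
#'
#' Isotropic Gaussian blur with `sigma = fwhm / (2 * sqrt(2 * log(2)))`,
#' applied by circular FFT convolution (the shapes sit on a uniform black
#' surround, so wrap-around is inert).
#'
#' @param image Numeric matrix.
#' @param fwhm Full width at half maximum of the kernel, in pixels.
#' @return Blurred numeric matrix of the same size.
#' @export
gaussian_blur <- function(image, fwhm) {
  stopifnot(is.matrix(image), fwhm > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  h <- nrow(image); w <- ncol(image)
  # wrapped (circular) coordinates so the kernel is centered at [1, 1]
  dy <- pmin(0:(h - 1), h - (0:(h - 1)))
  dx <- pmin(0:(w - 1), w - (0:(w - 1)))
  ky <- exp(-dy^2 / (2 * sigma^2))
  kx <- exp(-dx^2 / (2 * sigma^2))
  kern <- outer(ky, kx)
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(image) * stats::fft(kern), inverse = TRUE)) / (h * w)
}

#' Preprocess a shape image for the simulated-V1 model
#'
#' Gaussian low-pass (default FWHM 20 px, about the rat's acuity limit at the
#' viewing geometry used here) followed by whole-image z-normalization to
#' zero mean and unit standard deviation.
#'
#' @param image A `shape_image` or numeric matrix.
#' @param fwhm Blur FWHM in pixels.
#' @return Numeric matrix with mean 0 and SD 1.
#' @export
preprocess_image <- function(image, fwhm = 20) {
  m <- if (inherits(image, "shape_image")) image$raster + 0 else image
  sm <- gaussian_blur(m, fwhm)
  s <- stats::sd(sm)
  if (!is.finite(s) || s == 0) stop("constant image: zero SD after blur")
  (sm - mean(sm)) / s
}

# --- Filter bank ------------------------------------------------------------

#' Build the oriented filter bank
#'
#' One filter per (frequency, orientation) combination: a cosine-phase
#' oriented sinusoid under an isotropic Gaussian envelope (sigma = support/4),
#' with the square support sized to contain two cycles
#' (`ceiling(2 * px_per_deg / freq)` pixels). Every filter is normalized to
#' zero mean and unit Euclidean norm. The defaults (five frequencies from
#' 0.04 to 0.60 cpd, 16 orientations spanning the full circle) give 80
#' filters.
#'
#' @param freqs_cpd Spatial frequencies in cycles per degree.
#' @param n_orient Number of orientations, evenly spaced on `[0, 2 * pi)`.
#' @param px_per_deg Pixels per degree.
#' @param max_support Optional cap; an error is raised if any filter support
#'   exceeds it (e.g. the image size).
#' @return A `v1_filter_bank`: list of filters, each with `freq_cpd`,
#'   `orientation`, `support`, and `coefficients`.
#' @export
build_filter_bank <- function(freqs_cpd = c(0.04, 0.08, 0.15, 0.30, 0.60),
                              n_orient = 16L,
                              px_per_deg = DEFAULT_PX_PER_DEG,
                              max_support = NULL) {
  stopifnot(all(freqs_cpd > 0), n_orient >= 1L, px_per_deg > 0)
  filters <- list()
  for (f in freqs_cpd) {
    support <- as.integer(ceiling(2 * px_per_deg / f))
    if (!is.null(max_support) && support > max_support) {
      stop(sprintf(
        "filter support %d px for %.3f cpd exceeds %d px; downsample the image or drop the frequency",
        support, f, max_support
      ))
    }
    ctr <- (support + 1) / 2
    x <- outer(rep(1, support), seq_len(support) - ctr)
    y <- outer(seq_len(support) - ctr, rep(1, support))
    sigma <- support / 4
    env <- exp(-(x^2 + y^2) / (2 * sigma^2))
    f_px <- f / px_per_deg  # cycles per pixel
    for (k in seq_len(n_orient)) {
      theta <- 2 * pi * (k - 1) / n_orient
      carrier <- cos(2 * pi * f_px * (x * cos(theta) + y * sin(theta)))
      g <- env * carrier
      g <- g - mean(g)
      g <- g / sqrt(sum(g^2))
      filters[[length(filters) + 1L]] <- list(
        freq_cpd = f, orientation = theta, support = support, coefficients = g
      )
    }
  }
  structure(list(filters = filters, px_per_deg = px_per_deg),
            class = "v1_filter_bank")
}

#' @export
print.v1_filter_bank <- function(x, ...) {
  fr <- vapply(x$filters, `[[`, numeric(1), "freq_cpd")
  cat(sprintf("<v1_filter_bank> %d filters, %d frequencies x %d orientations\n",
              length(x$filters), length(unique(fr)),
              length(x$filters) / length(unique(fr))))
  invisible(x)
}

# Full (zero-padded linear) 2-D convolution via FFT; output size
# (nrow(a) + nrow(k) - 1) x (ncol(a) + ncol(k) - 1).
convolve_full <- function(image, kernel) {
  p1 <- next_fast_size(nrow(image) + nrow(kernel) - 1L)
  p2 <- next_fast_size(ncol(image) + ncol(kernel) - 1L)
  A <- matrix(0, p1, p2); A[seq_len(nrow(image)), seq_len(ncol(image))] <- image
  K <- matrix(0, p1, p2); K[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (p1 * p2)
  full[seq_len(nrow(image) + nrow(kernel) - 1L),
       seq_len(ncol(image) + ncol(kernel) - 1L)]
}

# Streaming cross-products between filter-response stacks, accumulated in the
# frequency domain. For zero-mean filters every response plane of the full
# linear convolution has an exactly zero sum, so Pearson correlations over
# the concatenated stacks reduce to the Parseval sums accumulated here: the
# full 80-plane stacks are never materialized.
response_stack_crossprods <- function(images, bank) {
  n_img <- length(images)
  S <- matrix(0, n_img, n_img)
  supports <- vapply(bank$filters, `[[`, integer(1), "support")
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  for (s in unique(supports)) {
    p1 <- next_fast_size(h + s - 1L)
    p2 <- next_fast_size(w + s - 1L)
    # summed filter power spectrum over this support's orientations
    Wk <- matrix(0, p1, p2)
    for (flt in bank$filters[supports == s]) {
      K <- matrix(0, p1, p2)
      K[seq_len(s), seq_len(s)] <- flt$coefficients
      Fk <- stats::fft(K)
      Wk <- Wk + Re(Fk)^2 + Im(Fk)^2
    }
    hats <- lapply(images, function(img) {
      A <- matrix(0, p1, p2)
      A[seq_len(h), seq_len(w)] <- img
      stats::fft(A)
    })
    for (n in seq_len(n_img)) {
      for (m in n:n_img) {
        cross <- Re(hats[[n]]) * Re(hats[[m]]) + Im(hats[[n]]) * Im(hats[[m]])
        S[n, m] <- S[n, m] + sum(cross * Wk) / (p1 * p2)
        S[m, n] <- S[n, m]
      }
    }
  }
  S
}

# Reference path: materialize the full-convolution response planes and
# correlate the concatenated stacks directly. Quadratic in image size; meant
# for small inputs and as the whole-stack check for the streaming engine.
response_stack_correlation_direct <- function(img_a, img_b, bank) {
  ra <- unlist(lapply(bank$filters, function(f) {
    as.numeric(convolve_full(img_a, f$coefficients))
  }))
  rb <- unlist(lapply(bank$filters, function(f) {
    as.numeric(convolve_full(img_b, f$coefficients))
  }))
  stats::cor(ra, rb)
}

#' Simulated-V1 dissimilarity (V1Sim)
#'
#' Each preprocessed shape image is convolved with every filter in the bank;
#' discriminability for a pair is `D = 1 - cor(R_n, R_m)` where the
#' correlation runs over the concatenation of all filter-response planes. The
#' 15-element D vector is then rescaled to (0.5, 1] as for PIX.
#'
#' @param set A `stimulus_set`.
#' @param bank A `v1_filter_bank` built at the same `px_per_deg` (default:
#'   [build_filter_bank()]).
#' @param fwhm Preprocessing blur FWHM in pixels.
#' @param engine `"fft"` (streaming frequency-domain accumulation, the
#'   default) or `"direct"` (materializes response planes; small images only).
#' @return A unit-interval `dissimilarity_vector` (source `"v1sim"`), with
#'   the raw D values in `attr(, "raw_d")` and pairwise response-stack
#'   correlations in `attr(, "stack_cor")`.
#' @export
v1sim_dissimilarity <- function(set, bank = NULL, fwhm = 20,
                                engine = c("fft", "direct")) {
  stopifnot(inherits(set, "stimulus_set"))
  engine <- match.arg(engine)
  if (is.null(bank)) bank <- build_filter_bank(px_per_deg = set$px_per_deg)
  imgs <- lapply(set$shapes, preprocess_image, fwhm = fwhm)
  idx <- set$pair_index
  if (engine == "fft") {
    S <- response_stack_crossprods(imgs, bank)
    if (any(diag(S) <= 0)) stop("degenerate zero-variance response stack")
    r <- vapply(seq_len(nrow(idx)), function(k) {
      S[idx$n[k], idx$m[k]] / sqrt(S[idx$n[k], idx$n[k]] * S[idx$m[k], idx$m[k]])
    }, numeric(1))
  } else {
    r <- vapply(seq_len(nrow(idx)), function(k) {
      response_stack_correlation_direct(imgs[[idx$n[k]]], imgs[[idx$m[k]]], bank)
    }, numeric(1))
  }
  d <- 1 - r
  out <- rescale_unit(new_dissimilarity(d, scale = "raw", source = "v1sim",
                                        n_shapes = length(set$shapes)))
  attr(out, "source") <- "v1sim"
  attr(out, "raw_d") <- d
  attr(out, "stack_cor") <- r
  out
}

#' Write a dissimilarity vector as CSV
#'
#' @param vec A `dissimilarity_vector`.
#' @param path Output CSV path.
#' @param raw Optional raw values to include alongside the (possibly
#'   rescaled) `vec`.
#' @export
write_dissimilarity <- function(vec, path, raw = NULL) {
  idx <- pair_index(6L)
  df <- data.frame(
    n = idx$n, m = idx$m,
    value = as.numeric(vec),
    scale = attr(vec, "scale") %||% "raw",
    source = attr(vec, "source") %||% "other"
  )
  if (!is.null(raw)) df$raw <- as.numeric(raw)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
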
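# Stimulus rendering: six binary shapes on a black background, drawn as
# outline strokes and luminance-equalized by tuning each shape's stroke width.

GLYPH_IDS <- c("square", "diamond_in_square", "triangle", "lambda",
               "letter_H", "plus")

# Default pixels per degree of visual angle for the recording display
# (1280 px spanning 102 deg of azimuth).
DEFAULT_PX_PER_DEG <- 1280 / 102

# Per-shape bounding-box widths (degrees). Only the mean (27.3) and the range
# (23-33) are constrained; compact glyphs get the smaller widths, and glyphs
# that share skeleton strokes (the square inside the diamond-in-square, the
# crossbar of H and plus) share a width so the shared strokes coincide on the
# pixel grid as they do in the original line drawings. Configurable via
# shape_spec()/default_shape_specs().
DEFAULT_BBOX_WIDTHS <- c(
  square = 24, diamond_in_square = 24, triangle = 27,
  lambda = 31.8, letter_H = 24, plus = 33
)

# Glyph skeletons: line segments (x0, y0, x1, y1) in a unit box
# [-0.5, 0.5]^2, y up. Every glyph spans the full [-0.5, 0.5] range in x so
# that the rendered bounding-box width is controlled exactly by the scale.
glyph_segments <- function(glyph_id) {
  seg <- function(...) matrix(c(...), ncol = 4L, byrow = TRUE,
                              dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  sq <- seg(
    -0.5, -0.5,  0.5, -0.5,
     0.5, -0.5,  0.5,  0.5,
     0.5,  0.5, -0.5,  0.5,
    -0.5,  0.5, -0.5, -0.5
  )
  switch(glyph_id,
    square = sq,
    diamond_in_square = rbind(sq, seg(
       0.0, -0.5,  0.5,  0.0,
       0.5,  0.0,  0.0,  0.5,
       0.0,  0.5, -0.5,  0.0,
      -0.5,  0.0,  0.0, -0.5
    )),
    triangle = seg(
      -0.5, -0.5,  0.5, -0.5,
       0.5, -0.5,  0.0,  0.5,
       0.0,  0.5, -0.5, -0.5
    ),
    lambda = seg(
      -0.5,  0.5,  0.5, -0.5,   # long descending stroke
       0.0,  0.0, -0.5, -0.5    # leg branching from the midpoint
    ),
    letter_H = seg(
      -0.5, -0.5, -0.5,  0.5,
       0.5, -0.5,  0.5,  0.5,
      -0.5,  0.0,  0.5,  0.0
    ),
    plus = seg(
      -0.5,  0.0,  0.5,  0.0,
       0.0, -0.5,  0.0,  0.5
    ),
    stop("unknown glyph_id: ", glyph_id)
  )
}

#' Specify one shape stimulus
#'
#' @param glyph_id One of `"square"`, `"diamond_in_square"`, `"triangle"`,
#'   `"lambda"`, `"letter_H"`, `"plus"`.
#' @param target_bbox_width Width of the minimal bounding box around the white
#'   pixels, in degrees of visual angle (23-33).
#' @param stroke_width Stroke thickness in pixels; the free parameter used for
#'   luminance equalization.
#' @return A `shape_spec` list.
#' @export
shape_spec <- function(glyph_id, target_bbox_width, stroke_width = 30) {
  glyph_id <- match.arg(glyph_id, GLYPH_IDS)
  stopifnot(target_bbox_width >= 23, target_bbox_width <= 33,
            stroke_width > 0)
  structure(
    list(glyph_id = glyph_id, target_bbox_width = target_bbox_width,
         stroke_width = stroke_width),
    class = "shape_spec"
  )
}

#' Default specifications for the six-shape set
#'
#' @param bbox_widths Named numeric vector of per-shape bounding-box widths in
#'   degrees; must cover all six glyphs.
#' @return List of six `shape_spec` objects.
#' @export
default_shape_specs <- function(bbox_widths = DEFAULT_BBOX_WIDTHS) {
  stopifnot(all(GLYPH_IDS %in% names(bbox_widths)))
  lapply(GLYPH_IDS, function(g) shape_spec(g, bbox_widths[[g]]))
}

#' Render a shape as a binary raster
#'
#' Draws the glyph's stroke skeleton, scaled so the rendered bounding box of
#' white pixels matches `target_bbox_width` to within one pixel, centered on
#' an all-black canvas. A pixel is white when its center lies within half the
#' stroke width of any skeleton segment.
#'
#' @param spec A [shape_spec()].
#' @param canvas_height,canvas_width Canvas size in pixels (defaults
#'   768 x 1280, the full display).
#' @param px_per_deg Pixels per degree of visual angle.
#' @return A `shape_image`: list with `glyph_id`, binary integer matrix
#'   `raster` (1 = white), and `px_per_deg`.
#' @export
render_shape <- function(spec, canvas_height = 768L, canvas_width = 1280L,
                         px_per_deg = DEFAULT_PX_PER_DEG) {
  stopifnot(inherits(spec, "shape_spec"), px_per_deg > 0)
  w_target <- round(spec$target_bbox_width * px_per_deg)
  t <- spec$stroke_width
  # half-extent of the white region; the -0.25 margin keeps pixel centers
  # strictly inside/outside so the discrete width equals w_target exactly
  r_eff <- w_target / 2 - 0.25
  scale <- 2 * r_eff - t           # skeleton span in px (strokes add t/2 each side)
  if (scale <= 0) {
    stop(sprintf("stroke width %.1f px too thick for glyph '%s' at %d px bbox",
                 t, spec$glyph_id, w_target))
  }
  # glyph center: half-integer x for even target widths, integer for odd, so
  # the symmetric white extent discretizes to exactly w_target columns
  cx <- if (w_target %% 2L == 0L) floor((canvas_width + 1) / 2) + 0.5
        else floor((canvas_width + 1) / 2)
  cy <- if (w_target %% 2L == 0L) floor((canvas_height + 1) / 2) + 0.5
        else floor((canvas_height + 1) / 2)
  half_span <- r_eff + 1
  if (cx - half_span < 1 || cx + half_span > canvas_width ||
      cy - half_span < 1 || cy + half_span > canvas_height) {
    stop(sprintf(
      "glyph '%s' (%d px bounding box) exceeds the %d x %d canvas",
      spec$glyph_id, w_target, canvas_height, canvas_width
    ))
  }
  field <- stroke_distance_field(spec$glyph_id, scale, cx, cy, half_t = t / 2,
                                 canvas_height, canvas_width)
  raster <- matrix(0L, canvas_height, canvas_width)
  raster[field <= t / 2] <- 1L
  if (!any(raster == 1L)) stop("rendered raster has no foreground pixels")
  structure(
    list(glyph_id = spec$glyph_id, raster = raster, px_per_deg = px_per_deg),
    class = "shape_image"
  )
}

# Distance from every pixel center to the nearest skeleton segment,
# evaluated only within each segment's reach (Inf elsewhere).
stroke_distance_field <- function(glyph_id, scale, cx, cy, half_t,
                                  canvas_height, canvas_width) {
  segs <- glyph_segments(glyph_id)
  field <- matrix(Inf, canvas_height, canvas_width)
  margin <- half_t + 2
  for (s in seq_len(nrow(segs))) {
    x0 <- cx + segs[s, "x0"] * scale; y0 <- cy - segs[s, "y0"] * scale
    x1 <- cx + segs[s, "x1"] * scale; y1 <- cy - segs[s, "y1"] * scale
    jmin <- max(1L, floor(min(x0, x1) - margin))
    jmax <- min(canvas_width, ceiling(max(x0, x1) + margin))
    imin <- max(1L, floor(min(y0, y1) - margin))
    imax <- min(canvas_height, ceiling(max(y0, y1) + margin))
    jj <- jmin:jmax; ii <- imin:imax
    px <- outer(rep(1, length(ii)), jj)   # x coordinate of each pixel center
    py <- outer(ii, rep(1, length(jj)))   # y coordinate (row index, y down)
    dx <- x1 - x0; dy <- y1 - y0
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - x0)^2 + (py - y0)^2
    } else {
      tt <- pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
      d2 <- (px - x0 - tt * dx)^2 + (py - y0 - tt * dy)^2
    }
    field[ii, jj] <- pmin(field[ii, jj], sqrt(d2))
  }
  field
}

#' Bounding-box width of a shape image, in degrees
#'
#' Width of the minimal rectangle containing all white pixels:
#' `(max_col - min_col + 1) / px_per_deg`.
#'
#' @param image A `shape_image`.
#' @return Width in degrees of visual angle.
#' @export
bbox_width_deg <- function(image) {
  stopifnot(inherits(image, "shape_image"))
  cols <- which(colSums(image$raster) > 0)
  if (length(cols) == 0L) stop("image has no foreground pixels")
  (max(cols) - min(cols) + 1) / image$px_per_deg
}

white_count <- function(image) sum(image$raster)

#' Build a luminance-equalized stimulus set
#'
#' Renders all six shapes and iteratively adjusts each shape's stroke width
#' (by bisection; white-pixel count is monotone in stroke width) until every
#' shape's white-pixel count lies within `luminance_tol` of the median count
#' of the initially rendered set. Bounding-box widths are unaffected by the
#' stroke adjustment because the skeleton is rescaled to keep the outer extent
#' fixed.
#'
#' @param specs List of six `shape_spec`s with distinct glyphs (default
#'   [default_shape_specs()]).
#' @param canvas_height,canvas_width,px_per_deg Passed to [render_shape()].
#' @param luminance_tol Relative tolerance on white-pixel counts (default
#'   0.01).
#' @param max_iter Bisection iterations per shape.
#' @return A `stimulus_set`: list with `shapes` (six `shape_image`s),
#'   `pair_index` (the canonical 15-pair table), `px_per_deg`,
#'   `white_counts`, and the equalized `stroke_widths`.
#' @export
build_stimulus_set <- function(specs = default_shape_specs(),
                               canvas_height = 768L, canvas_width = 1280L,
                               px_per_deg = DEFAULT_PX_PER_DEG,
                               luminance_tol = 0.01, max_iter = 40L) {
  stopifnot(length(specs) == 6L)
  ids <- vapply(specs, function(s) s$glyph_id, character(1))
  if (anyDuplicated(ids)) stop("glyph_ids must be distinct")

  # initial strokes scaled by inverse skeleton length so counts start close
  lens <- vapply(specs, function(s) {
    g <- glyph_segments(s$glyph_id)
    sum(sqrt((g[, "x1"] - g[, "x0"])^2 + (g[, "y1"] - g[, "y0"])^2))
  }, numeric(1))
  strokes <- vapply(seq_along(specs), function(i) {
    specs[[i]]$stroke_width * 4 / lens[i]
  }, numeric(1))
  counts <- vapply(seq_along(specs), function(i) {
    sp <- specs[[i]]; sp$stroke_width <- strokes[i]
    white_count(render_shape(sp, canvas_height, canvas_width, px_per_deg))
  }, numeric(1))
  target <- round(stats::median(counts))

  # Per shape, solve for the stroke width whose distance threshold admits
  # exactly `target` pixels. Axis-aligned strokes make the count jump by
  # whole pixel rows as the threshold crosses the grid, so the threshold is
  # taken as the target-th smallest skeleton distance, with ties broken in
  # stable scan order; a few fixed-point iterations reconcile the stroke
  # width with the bbox-preserving skeleton rescaling.
  shapes <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    w_target <- round(sp$target_bbox_width * px_per_deg)
    r_eff <- w_target / 2 - 0.25
    cx <- if (w_target %% 2L == 0L) floor((canvas_width + 1) / 2) + 0.5
          else floor((canvas_width + 1) / 2)
    cy <- if (w_target %% 2L == 0L) floor((canvas_height + 1) / 2) + 0.5
          else floor((canvas_height + 1) / 2)
    t <- strokes[i]
    field <- NULL
    for (it in seq_len(max_iter)) {
      scale <- 2 * r_eff - t
      if (scale <= 0) stop("stroke too thick for glyph ", sp$glyph_id)
      field <- stroke_distance_field(sp$glyph_id, scale, cx, cy, t / 2 + 4,
                                     canvas_height, canvas_width)
      t_new <- 2 * sort(field, partial = target)[target]
      if (abs(t_new - t) < 0.05) { t <- t_new; break }
      t <- t_new
    }
    scale <- 2 * r_eff - t
    field <- stroke_distance_field(sp$glyph_id, scale, cx, cy, t / 2 + 4,
                                   canvas_height, canvas_width)
    raster <- matrix(0L, canvas_height, canvas_width)
    raster[order(field)[seq_len(target)]] <- 1L
    strokes[i] <- t
    shapes[[i]] <- structure(
      list(glyph_id = sp$glyph_id, raster = raster, px_per_deg = px_per_deg),
      class = "shape_image"
    )
  }
  names(shapes) <- ids
  counts <- vapply(shapes, white_count, numeric(1))
  med <- stats::median(counts)
  if (any(abs(counts - med) > luminance_tol * med)) {
    stop(sprintf(
      "luminance equalization did not converge: residual spread %.3f%% > %.3f%%",
      100 * max(abs(counts - med) / med), 100 * luminance_tol
    ))
  }
  structure(
    list(shapes = shapes, pair_index = pair_index(6L),
         px_per_deg = px_per_deg, white_counts = counts,
         stroke_widths = stats::setNames(strokes, ids)),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set> 6 shapes,", nrow(x$pair_index), "pairs\n")
  cat(sprintf("  px_per_deg = %.4f\n", x$px_per_deg))
  w <- vapply(x$shapes, bbox_width_deg, numeric(1))
  cat(sprintf("  bbox widths (deg): %s (mean %.2f)\n",
              paste(sprintf("%.1f", w), collapse = ", "), mean(w)))
  cat(sprintf("  white counts: %s\n",
              paste(x$white_counts, collapse = ", ")))
  invisible(x)
}

#' Stimulus presentation conditions
#'
#' During recordings each shape translated along four movement axes whose
#' order was shuffled per trial; crossing the six shapes with the four axis
#' orders gives 24 presentation conditions.
#'
#' @param n_axis_orders Number of distinct axis orders (default 4).
#' @return Data frame with columns `glyph_id` and `axis_order` (24 rows for
#'   the defaults).
#' @export
stimulus_conditions <- function(n_axis_orders = 4L) {
  expand.grid(glyph_id = GLYPH_IDS, axis_order = seq_len(n_axis_orders),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Write a stimulus set as PNG files plus a JSON manifest
#'
#' @param set A `stimulus_set`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_stimulus_set <- function(set, dir) {
  stopifnot(inherits(set, "stimulus_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (id in names(set$shapes)) {
    f <- file.path(dir, paste0(id, ".png"))
    png::writePNG(set$shapes[[id]]$raster * 1.0, f)  # 8-bit gray, white = 255
    files[id] <- basename(f)
  }
  manifest <- list(
    px_per_deg = set$px_per_deg,
    shapes = lapply(names(set$shapes), function(id) list(
      glyph_id = id, file = files[[id]],
      white_count = unname(set$white_counts[[id]]),
      stroke_width = unname(set$stroke_widths[[id]])
    ))
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Read a stimulus set written by [write_stimulus_set()]
#'
#' @param dir Directory containing the PNGs and `manifest.json`.
#' @return A `stimulus_set`.
#' @export
read_stimulus_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ppd <- manifest$px_per_deg
  shapes <- list()
  strokes <- counts <- numeric(0)
  for (entry in manifest$shapes) {
    img <- png::readPNG(file.path(dir, entry$file))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    shapes[[entry$glyph_id]] <- structure(
      list(glyph_id = entry$glyph_id,
           raster = matrix(as.integer(img > 0.5), nrow(img), ncol(img)),
           px_per_deg = ppd),
      class = "shape_image"
    )
    strokes[entry$glyph_id] <- entry$stroke_width
    counts[entry$glyph_id] <- entry$white_count
  }
  structure(
    list(shapes = shapes, pair_index = pair_index(6L), px_per_deg = ppd,
         white_counts = counts, stroke_widths = strokes),
    class = "stimulus_set"
  )
}
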
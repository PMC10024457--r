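# Cell-scale morphology metrics from traced polygons and the depth map.
#
# Margin undulation is the ratio of the traced cell area to the area of its
# convex hull (1 for a perfectly round/convex cell).  The cell cap aspect
# ratio divides the cell width -- twice the planar peak-to-valley distance,
# exactly as defined -- by the cell height (peak minus valley depth).  Five
# tracings per sample are averaged.

#' Construct a validated cell trace
#'
#' @param vertices Two-column matrix or data frame of polygon vertices in
#'   pixel coordinates (`x_px`, `y_px`), ordered along the boundary.  A
#'   closing vertex equal to the first is dropped.
#' @param magnification Optional magnification tag (e.g. 500).
#' @param validate Check that the polygon is simple (no self-intersection).
#'
#' @return An object of class `leafpol_cell_trace`.
#' @export
cell_trace <- function(vertices, magnification = NULL, validate = TRUE) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || !is.numeric(v) || any(!is.finite(v)))
    stop_geom("`vertices` must be a finite two-column matrix")
  n <- nrow(v)
  if (n >= 2L && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L) stop_geom("a cell trace needs at least 3 distinct vertices")
  if (validate && !is_simple_polygon(v))
    stop_geom("cell trace is self-intersecting (polygon must be simple)")
  structure(list(vertices = v, magnification = magnification),
            class = "leafpol_cell_trace")
}

as_trace <- function(x) {
  if (inherits(x, "leafpol_cell_trace")) x else cell_trace(x)
}

# Shoelace area (absolute value) of an open polygon ring.
shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Proper-crossing test for all non-adjacent edge pairs (O(n^2), fine for
# hand-traced cells).
is_simple_polygon <- function(v) {
  n <- nrow(v)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j - i <= 1L) next
      p1 <- v[i, ]; p2 <- v[i %% n + 1L, ]
      p3 <- v[j, ]; p4 <- v[j %% n + 1L, ]
      d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
      d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(FALSE)
    }
  }
  TRUE
}

# Rasterize a polygon onto an nr x nc pixel grid (even-odd rule on pixel
# centers); used as the pixel-counting area alternative and to index the
# depth map inside a trace.
polygon_mask <- function(v, nr, nc) {
  px <- rep(seq_len(nc), each = nr)
  py <- rep(seq_len(nr), times = nc)
  inside <- logical(nr * nc)
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nr, nc)
}

#' Cell size from a traced polygon
#'
#' Area of the traced cell in square micrometers.  The default continuous
#' (shoelace) area is resolution-independent; `method = "pixel"` counts
#' rasterized pixel centers instead, mirroring a pixel-counting workflow.
#'
#' @param trace A [cell_trace()] (or coercible vertex matrix).
#' @param pixel_scale mm/pixel calibration (default 500x value `9.8e-5`).
#' @param method `"shoelace"` (default) or `"pixel"`.
#'
#' @return Cell area in square micrometers.
#' @export
#' @examples
#' sq <- cell_trace(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' cell_size(sq, pixel_scale = 9.8e-5)  # 96.04 um^2
cell_size <- function(trace, pixel_scale = 9.8e-5,
                      method = c("shoelace", "pixel")) {
  trace <- as_trace(trace)
  method <- match.arg(method)
  check_scalar(pixel_scale, "pixel_scale", positive = TRUE)
  v <- trace$vertices
  a_px <- if (method == "shoelace") {
    shoelace_area(v)
  } else {
    nr <- ceiling(max(v[, 2])) + 1L
    nc <- ceiling(max(v[, 1])) + 1L
    sum(polygon_mask(v, nr, nc))
  }
  if (a_px <= 0) stop_geom("traced polygon has zero area")
  a_px * (pixel_scale * 1000)^2
}

#' Margin undulation of a traced cell
#'
#' Ratio of the traced cell area to the area of its convex hull.  Bounded in
#' `(0, 1]`; equals 1 exactly when the trace is convex (a completely round
#' cell), and decreases as the cell margin undulates.
#'
#' @inheritParams cell_size
#' @return Dimensionless ratio in `(0, 1]`.
#' @export
#' @examples
#' star <- cbind(c(1, 0.354, 0, -0.354, -1, -0.354, 0, 0.354),
#'               c(0, 0.354, 1, 0.354, 0, -0.354, -1, -0.354))
#' margin_undulation(cell_trace(star))  # about 0.707
margin_undulation <- function(trace) {
  trace <- as_trace(trace)
  v <- trace$vertices
  a1 <- shoelace_area(v)
  hull <- v[grDevices::chull(v[, 1], v[, 2]), , drop = FALSE]
  a2 <- shoelace_area(hull)
  if (a2 <= 0) stop_geom("convex hull of the trace has zero area")
  a1 / a2
}

#' Cell cap aspect ratio from peak/valley coordinates
#'
#' Width over height of a cell cap: width is twice the planar distance
#' between the highest and lowest point inside the cell (converted to mm by
#' the pixel scale `c`), height is their depth difference in mm.
#'
#' @param peak,valley Numeric length-3 vectors `(x_px, y_px, z_mm)`.
#' @param pixel_scale Scaling factor `c` in mm/pixel.
#' @return Dimensionless width/height ratio.
#' @export
#' @examples
#' cap_ratio_from_points(c(0, 0, 0.01), c(100, 0, 0), 9.8e-5)  # 1.96
cap_ratio_from_points <- function(peak, valley, pixel_scale = 9.8e-5) {
  check_scalar(pixel_scale, "pixel_scale", positive = TRUE)
  dz <- peak[3] - valley[3]
  if (dz <= 0)
    stop_leafpol("cell height is zero (flat region): cap aspect ratio undefined",
                 "leafpol_flat_cell_error")
  width <- 2 * pixel_scale * sqrt((peak[1] - valley[1])^2 +
                                    (peak[2] - valley[2])^2)
  unname(width / dz)
}

#' Cell cap aspect ratio of a traced cell on a depth map
#'
#' Locates the maximum and minimum depth inside the traced polygon (peak and
#' valley) and applies [cap_ratio_from_points()].  Flat regions (zero height)
#' raise a `leafpol_flat_cell_error`, mirroring the exclusion of unmeasurable
#' cells from sample averages.
#'
#' @inheritParams cell_size
#' @param depth_mm Depth map matrix in mm (rows = y pixels, cols = x pixels).
#' @return A list with `ratio`, `peak`, and `valley` (each `(x_px, y_px,
#'   z_mm)`).
#' @export
cap_aspect_ratio <- function(trace, depth_mm, pixel_scale = 9.8e-5) {
  trace <- as_trace(trace)
  if (!is.matrix(depth_mm)) stop_dim("`depth_mm` must be a matrix")
  mask <- polygon_mask(trace$vertices, nrow(depth_mm), ncol(depth_mm))
  if (!any(mask)) stop_geom("trace does not overlap the depth map")
  z <- depth_mm
  z[!mask] <- NA
  i_pk <- which.max(z)
  i_vl <- which.min(z)
  pk <- c(x = (i_pk - 1L) %/% nrow(z) + 1L, y = (i_pk - 1L) %% nrow(z) + 1L,
          z = z[i_pk])
  vl <- c(x = (i_vl - 1L) %/% nrow(z) + 1L, y = (i_vl - 1L) %% nrow(z) + 1L,
          z = z[i_vl])
  list(ratio = cap_ratio_from_points(pk, vl, pixel_scale),
       peak = pk, valley = vl)
}

#' All morphology metrics for one traced cell
#'
#' @inheritParams cap_aspect_ratio
#' @param depth_mm Optional depth map; without it the cap aspect ratio is
#'   `NA`.
#' @return An object of class `leafpol_cell_metrics`: `cell_size_um2`,
#'   `margin_undulation`, `cap_aspect_ratio` (`NA` with `valid_cap = FALSE`
#'   for flat cells), `peak`, `valley`.
#' @export
cell_metrics <- function(trace, depth_mm = NULL, pixel_scale = 9.8e-5) {
  trace <- as_trace(trace)
  cap <- NA_real_; pk <- vl <- NULL; valid_cap <- FALSE
  if (!is.null(depth_mm)) {
    res <- tryCatch(cap_aspect_ratio(trace, depth_mm, pixel_scale),
                    leafpol_flat_cell_error = function(e) NULL)
    if (!is.null(res)) {
      cap <- res$ratio; pk <- res$peak; vl <- res$valley; valid_cap <- TRUE
    }
  }
  structure(list(cell_size_um2 = cell_size(trace, pixel_scale),
                 margin_undulation = margin_undulation(trace),
                 cap_aspect_ratio = cap, valid_cap = valid_cap,
                 peak = pk, valley = vl),
            class = "leafpol_cell_metrics")
}

#' Average metrics over a sample's tracings
#'
#' Five tracings per sample is the standard protocol; the summary is the
#' arithmetic mean of each metric over the valid tracings.  Tracings whose
#' cap aspect ratio is undefined (flat cell) contribute to the other metrics
#' only; the count of valid cap measurements is recorded.
#'
#' @param tracings List of `leafpol_cell_metrics`.
#' @param pubescence_coverage Optional percent pubescent coverage to attach.
#' @return An object of class `leafpol_sample_summary` with the per-sample
#'   means, `n_tracings`, `n_valid_cap`, `pubescence_coverage` and
#'   `usable_flag`.
#' @export
summarize_sample <- function(tracings, pubescence_coverage = NULL) {
  if (length(tracings) == 0L)
    stop_leafpol("no tracings supplied", "leafpol_summary_error")
  ok <- vapply(tracings, inherits, logical(1), "leafpol_cell_metrics")
  if (!all(ok)) stop_param("`tracings` must be a list of leafpol_cell_metrics")
  size <- vapply(tracings, `[[`, numeric(1), "cell_size_um2")
  und <- vapply(tracings, `[[`, numeric(1), "margin_undulation")
  cap <- vapply(tracings, `[[`, numeric(1), "cap_aspect_ratio")
  if (all(is.na(size)) && all(is.na(und)) && all(is.na(cap)))
    stop_leafpol("all tracings invalid: empty summary", "leafpol_summary_error")
  if (!is.null(pubescence_coverage)) {
    check_scalar(pubescence_coverage, "pubescence_coverage", nonneg = TRUE)
    if (pubescence_coverage > 100)
      stop_param("`pubescence_coverage` must be in [0, 100]")
  }
  structure(list(
    cell_size_um2 = mean(size, na.rm = TRUE),
    margin_undulation = mean(und, na.rm = TRUE),
    cap_aspect_ratio = if (all(is.na(cap))) NA_real_ else mean(cap, na.rm = TRUE),
    n_tracings = length(tracings),
    n_valid_cap = sum(!is.na(cap)),
    pubescence_coverage = pubescence_coverage,
    usable_flag = any(!is.na(size))
  ), class = "leafpol_sample_summary")
}

#' Percent pubescent coverage from a traced hair mask
#'
#' @param hair_mask Logical (or 0/1) matrix marking traced hair pixels.
#' @return Percent of the field covered, in `[0, 100]`.
#' @export
pubescence_coverage <- function(hair_mask) {
  if (!is.matrix(hair_mask) || length(hair_mask) == 0L)
    stop_dim("`hair_mask` must be a nonempty matrix")
  m <- hair_mask != 0
  100 * mean(m)
}

#' Approximate coverage from a hair count
#'
#' For leaves with high pubescent coverage (above about 25%) and small,
#' consistently sized trichomes, coverage can be approximated by counting
#' hairs and multiplying by the mean area of 5 sampled hairs.
#'
#' @param hair_count Number of hairs counted (>= 0).
#' @param sample_hair_areas Areas of exactly 5 individual hairs, pixels^2.
#' @param field_area Field area in pixels^2 (> 0).
#' @return Percent coverage.
#' @export
coverage_by_count <- function(hair_count, sample_hair_areas, field_area) {
  if (length(sample_hair_areas) != 5L)
    stop_param("`sample_hair_areas` must contain exactly 5 hair areas")
  check_scalar(hair_count, "hair_count", nonneg = TRUE)
  check_scalar(field_area, "field_area", positive = TRUE)
  100 * hair_count * mean(sample_hair_areas) / field_area
}
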
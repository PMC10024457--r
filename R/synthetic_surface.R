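# Synthetic leaf surface generator.
#
# Emulates the three roughness scales relevant at 500x magnification:
# periodic epidermal cell domes (microscopic roughness), optional trichome
# ridges (macroscopic roughness), and wax presentation (glossy wax fills the
# inter-cellular grooves to a smooth film; glaucous wax adds fine speckle to
# the texture).  Ground truth (height field, cell boundary polygons,
# trichome mask) is always retained for recovery tests downstream.

#' Specification of a synthetic leaf surface
#'
#' @param cell_pitch_um Center-to-center epidermal cell spacing, micrometers.
#' @param cell_amplitude_um Dome height of a cell above the groove floor,
#'   micrometers.  `0` gives a perfectly flat field.
#' @param margin_waviness Dimensionless in `[0, 1]`; `0` produces circular
#'   (convex) cell boundaries, larger values produce lobed, undulating
#'   margins.
#' @param trichome_density Target fraction of the field area covered by
#'   trichomes, in `[0, 1]`.
#' @param trichome_length_um Trichome length, micrometers.
#' @param trichome_orientation `"vertical"` (short erect hairs rendered as
#'   tall narrow bumps) or `"horizontal"` (hairs lying along the surface,
#'   rendered as long low ridges).
#' @param wax_mode `"none"`, `"glossy_fill"` (wax fills the grooves between
#'   cells, strictly reducing height variance), or `"glaucous_scatter"`
#'   (speckled bloom on the texture; height untouched).
#' @param field_size Field size in pixels, length 1 or 2 (rows, cols).
#' @param pixel_scale Pixel scale in mm/pixel.  Default `9.8e-5` mm/pixel
#'   (the 500x calibration).
#'
#' @return An object of class `leafpol_surface_spec`.
#' @seealso [generate_surface()]
#' @export
surface_spec <- function(cell_pitch_um = 25,
                         cell_amplitude_um = 3,
                         margin_waviness = 0.3,
                         trichome_density = 0,
                         trichome_length_um = 20,
                         trichome_orientation = c("vertical", "horizontal"),
                         wax_mode = c("none", "glossy_fill", "glaucous_scatter"),
                         field_size = c(192L, 192L),
                         pixel_scale = 9.8e-5) {
  check_scalar(cell_pitch_um, "cell_pitch_um", positive = TRUE)
  check_scalar(cell_amplitude_um, "cell_amplitude_um", nonneg = TRUE)
  check_scalar(margin_waviness, "margin_waviness", nonneg = TRUE)
  if (margin_waviness > 1) stop_param("`margin_waviness` must be in [0, 1]")
  check_scalar(trichome_density, "trichome_density", nonneg = TRUE)
  if (trichome_density > 1) stop_param("`trichome_density` must be in [0, 1]")
  check_scalar(trichome_length_um, "trichome_length_um", positive = TRUE)
  trichome_orientation <- match.arg(trichome_orientation)
  wax_mode <- match.arg(wax_mode)
  if (length(field_size) == 1L) field_size <- rep(field_size, 2L)
  if (length(field_size) != 2L || any(!is.finite(field_size)) ||
      any(field_size < 8))
    stop_param("`field_size` must be one or two positive pixel counts (>= 8)")
  check_scalar(pixel_scale, "pixel_scale", positive = TRUE)
  structure(list(
    cell_pitch_um = cell_pitch_um,
    cell_amplitude_um = cell_amplitude_um,
    margin_waviness = margin_waviness,
    trichome_density = trichome_density,
    trichome_length_um = trichome_length_um,
    trichome_orientation = trichome_orientation,
    wax_mode = wax_mode,
    field_size = as.integer(field_size),
    pixel_scale = pixel_scale
  ), class = "leafpol_surface_spec")
}

#' Generate a synthetic leaf surface with known ground truth
#'
#' Builds a height field (mm) of periodic epidermal cell domes with
#' configurable margin undulation, optional trichome ridges and wax
#' treatment, together with a reflectance texture image suitable for focus
#' stacking.  The boundary polygon of every complete cell is returned so
#' trace-based morphology metrics can be tested against known geometry.
#'
#' @param spec A [surface_spec()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#'
#' @return An object of class `leafpol_surface`: a list with `height_mm`
#'   (matrix), `texture` (matrix in `[0, 1]`), `trichome_mask` (logical
#'   matrix), `n_trichomes` and `trichome_areas_px2` (stamped-hair ground
#'   truth), `cell_polygons` (list of data frames with `x_px`, `y_px`),
#'   `spec`, and `seed`.
#' @export
#' @examples
#' surf <- generate_surface(surface_spec(field_size = 64, pixel_scale = 1e-3),
#'                          seed = 1)
#' range(surf$height_mm)
generate_surface <- function(spec, seed = 1L) {
  if (!inherits(spec, "leafpol_surface_spec"))
    spec <- do.call(surface_spec, as.list(spec))
  with_seed(seed, {
    nr <- spec$field_size[1L]; nc <- spec$field_size[2L]
    ps <- spec$pixel_scale
    pitch_px <- spec$cell_pitch_um * 1e-3 / ps
    amp_mm <- spec$cell_amplitude_um * 1e-3

    X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    Y <- matrix(seq_len(nr), nr, nc)

    # square lattice of cell centers at half-integer multiples of the pitch
    ix <- floor(X / pitch_px); iy <- floor(Y / pitch_px)
    cx <- (ix + 0.5) * pitch_px; cy <- (iy + 0.5) * pitch_px
    n_ix <- max(ix) + 1L; n_iy <- max(iy) + 1L

    # per-cell margin randomness: lobe count and phase
    lobes <- matrix(sample(4:7, n_iy * n_ix, replace = TRUE), n_iy, n_ix)
    phase <- matrix(stats::runif(n_iy * n_ix, 0, 2 * pi), n_iy, n_ix)

    dx <- X - cx; dy <- Y - cy
    d <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    cell_id <- cbind(as.vector(iy) + 1L, as.vector(ix) + 1L)
    k <- matrix(lobes[cell_id], nr, nc)
    ph <- matrix(phase[cell_id], nr, nc)
    r_cell <- 0.45 * pitch_px *
      (1 + 0.25 * spec$margin_waviness * sin(k * phi + ph))
    prof <- cos(pmin(d / r_cell, 1) * (pi / 2))
    height <- amp_mm * prof

    texture <- 0.45 + 0.35 * prof +
      matrix(stats::runif(nr * nc, -0.06, 0.06), nr, nc)

    # trichomes: stamp hairs until the mask reaches the target density
    mask <- matrix(FALSE, nr, nc)
    tri_areas <- integer(0)
    if (spec$trichome_density > 0) {
      len_px <- max(2, spec$trichome_length_um * 1e-3 / ps)
      width_px <- max(1, 2.5e-3 / ps * 1)  # ~2.5 um wide hairs
      tri_h_mm <- spec$trichome_length_um * 1e-3
      for (i in seq_len(5000L)) {
        if (mean(mask) >= spec$trichome_density) break
        x0 <- stats::runif(1, 1, nc); y0 <- stats::runif(1, 1, nr)
        if (spec$trichome_orientation == "vertical") {
          # erect hair seen from above: a small raised disk
          hit <- (X - x0)^2 + (Y - y0)^2 <= (1.5 * width_px)^2
          height[hit] <- height[hit] + tri_h_mm
        } else {
          # hair lying on the surface: a long thin raised ridge
          th <- stats::runif(1, 0, pi)
          u <- c(cos(th), sin(th))
          t_along <- (X - x0) * u[1] + (Y - y0) * u[2]
          t_perp <- -(X - x0) * u[2] + (Y - y0) * u[1]
          hit <- abs(t_along) <= len_px / 2 & abs(t_perp) <= width_px
          height[hit] <- height[hit] + 2.5e-3  # ridge as tall as it is wide
        }
        mask <- mask | hit
        texture[hit] <- 0.9
        tri_areas <- c(tri_areas, sum(hit))
      }
    }

    if (spec$wax_mode == "glossy_fill") {
      # wax fills the inter-cellular grooves up to a fraction of the dome
      height <- pmax(height, 0.55 * amp_mm)
      texture <- 0.5 * texture + 0.5 * mean(texture)  # smoother film
    } else if (spec$wax_mode == "glaucous_scatter") {
      texture <- texture + matrix(stats::runif(nr * nc, -0.12, 0.12), nr, nc) +
        0.05
    }
    texture <- pmin(pmax(texture, 0), 1)

    # boundary polygon of every cell whose center lies inside the field
    polys <- list()
    for (jy in seq_len(n_iy)) for (jx in seq_len(n_ix)) {
      ccx <- (jx - 0.5) * pitch_px; ccy <- (jy - 0.5) * pitch_px
      if (ccx < 1 || ccx > nc || ccy < 1 || ccy > nr) next
      ang <- seq(0, 2 * pi, length.out = 73L)[-73L]
      rr <- 0.45 * pitch_px *
        (1 + 0.25 * spec$margin_waviness * sin(lobes[jy, jx] * ang +
                                               phase[jy, jx]))
      polys[[length(polys) + 1L]] <-
        data.frame(x_px = ccx + rr * cos(ang), y_px = ccy + rr * sin(ang))
    }

    structure(list(height_mm = height, texture = texture,
                   trichome_mask = mask, n_trichomes = length(tri_areas),
                   trichome_areas_px2 = tri_areas, cell_polygons = polys,
                   spec = spec, seed = seed),
              class = "leafpol_surface")
  })
}
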
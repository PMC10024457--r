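# Polarized-reflectance feature extraction.
#
# A scan set holds 19 reflectance-factor spectra taken through a polarizer
# rotated 0..90 degrees in 5-degree steps at Brewster's-angle geometry.
# After dark-reference removal and normalization to the polarizer
# transmittance, the minimum and maximum spectra give the polarized BRF
# R_Q = (R_max - R_min)/2 and the total R = (R_max + R_min)/2 = R_Q + R_min.
# The two classification features are R_Qav (mean R_Q over 500-900 nm, which
# also averages out thin-film interference ripple) and DIFF_R (the diffuse
# spectrum ratio R_min(765)/R_min(680), spanning the red edge).

#' Polarizer orientation grid of a scan set
#'
#' The 19 polarizer orientations of a full sweep: 0 (parallel to the
#' incidence plane) to 90 degrees (perpendicular) in 5-degree steps.
#'
#' @return Numeric vector `seq(0, 90, by = 5)`.
#' @export
scan_orientations <- function() seq(0, 90, by = 5)

#' Construct a polarized scan set
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param reflectance Matrix `[wavelength x orientation]` of reflectance
#'   factors; 19 columns for polarizer orientations 0, 5, ..., 90 degrees.
#' @param orientations_deg Orientation angles; must be `seq(0, 90, 5)`.
#' @param dark_reference Dark reference spectrum on the same grid (default
#'   zeros, i.e. already removed).
#' @param polarizer_transmittance Polarizer transmittance spectrum measured
#'   with source and sensor aligned (default ones, i.e. already normalized).
#'
#' @return An object of class `leafpol_scanset`.
#' @export
polarized_scanset <- function(wavelength_nm, reflectance,
                              orientations_deg = scan_orientations(),
                              dark_reference = NULL,
                              polarizer_transmittance = NULL) {
  wavelength_nm <- as.numeric(wavelength_nm)
  if (any(diff(wavelength_nm) <= 0))
    stop_format("`wavelength_nm` must be strictly increasing")
  reflectance <- as.matrix(reflectance)
  if (nrow(reflectance) != length(wavelength_nm))
    stop_dim("reflectance rows must match the wavelength grid")
  if (!isTRUE(all.equal(as.numeric(orientations_deg), scan_orientations())))
    stop_format("orientations must be 0, 5, ..., 90 degrees (19 scans)")
  if (ncol(reflectance) != 19L)
    stop_format(sprintf("expected 19 orientation columns, got %d",
                        ncol(reflectance)))
  n <- length(wavelength_nm)
  dark_reference <- dark_reference %||% numeric(n)
  polarizer_transmittance <- polarizer_transmittance %||% rep(1, n)
  if (length(dark_reference) != n || length(polarizer_transmittance) != n)
    stop_dim("reference spectra must be on the scan wavelength grid")
  structure(list(wavelength_nm = wavelength_nm, reflectance = reflectance,
                 orientations_deg = scan_orientations(),
                 dark_reference = as.numeric(dark_reference),
                 polarizer_transmittance = as.numeric(polarizer_transmittance)),
            class = "leafpol_scanset")
}

#' @export
print.leafpol_scanset <- function(x, ...) {
  cat(sprintf("<leafpol_scanset> %d wavelengths %g..%g nm x 19 orientations\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  invisible(x)
}

#' Dark-correct and transmittance-normalize a scan set
#'
#' Each orientation column becomes `(raw - dark) / transmittance` per
#' wavelength.  The transmittance is floored at `1e-6` before division; if
#' it sits at or below the floor anywhere inside the feature window
#' (500-900 nm), normalization is refused.
#'
#' @param scans A [polarized_scanset()].
#' @param window Feature wavelength window checked for a usable
#'   transmittance, nm.
#' @return A `leafpol_scanset` with corrected reflectance and identity
#'   references.
#' @export
preprocess_scanset <- function(scans, window = c(500, 900)) {
  if (!inherits(scans, "leafpol_scanset"))
    stop_format("`scans` must be a leafpol_scanset")
  floor_t <- 1e-6
  tr <- scans$polarizer_transmittance
  in_win <- scans$wavelength_nm >= window[1] & scans$wavelength_nm <= window[2]
  if (any(tr[in_win] <= floor_t))
    stop_leafpol("polarizer transmittance at/below floor inside the feature window",
                 "leafpol_normalization_error")
  corrected <- (scans$reflectance - scans$dark_reference) / pmax(tr, floor_t)
  polarized_scanset(scans$wavelength_nm, corrected)
}

#' Select the minimum and maximum spectra of a scan set
#'
#' Because the leaf surface is never perfectly flat and aligned, the minimum
#' reflectance is not always at the nominal parallel (0 degree) orientation;
#' the extrema are therefore chosen from the measured scans.  The default
#' selects whole scans by their mean reflectance over the feature window
#' (preserving spectral shape for `DIFF_R`); `mode = "wavelength"` takes the
#' per-wavelength envelope instead.
#'
#' @param scans A (preprocessed) [polarized_scanset()].
#' @param window Window (nm) over which scan means are compared.
#' @param mode `"scan"` (default) or `"wavelength"`.
#' @return A list with `R_max`, `R_min` (spectra), `idx_min_deg`,
#'   `idx_max_deg` (orientation angles; vectors in `"wavelength"` mode), and
#'   `wavelength_nm`.
#' @export
select_extrema <- function(scans, window = c(500, 900),
                           mode = c("scan", "wavelength")) {
  if (!inherits(scans, "leafpol_scanset"))
    stop_format("`scans` must be a leafpol_scanset")
  mode <- match.arg(mode)
  R <- scans$reflectance
  th <- scans$orientations_deg
  if (mode == "scan") {
    in_win <- scans$wavelength_nm >= window[1] & scans$wavelength_nm <= window[2]
    if (!any(in_win))
      stop_leafpol("wavelength grid does not cover the feature window",
                   "leafpol_feature_wavelength_error")
    m <- colMeans(R[in_win, , drop = FALSE])
    i_min <- which.min(m)                       # ties toward 0 degrees
    i_max <- length(m) + 1L - which.max(rev(m)) # ties toward 90 degrees
    list(R_max = R[, i_max], R_min = R[, i_min],
         idx_min_deg = th[i_min], idx_max_deg = th[i_max],
         wavelength_nm = scans$wavelength_nm)
  } else {
    i_min <- apply(R, 1L, which.min)
    i_max <- apply(R, 1L, function(r) length(r) + 1L - which.max(rev(r)))
    list(R_max = R[cbind(seq_len(nrow(R)), i_max)],
         R_min = R[cbind(seq_len(nrow(R)), i_min)],
         idx_min_deg = th[i_min], idx_max_deg = th[i_max],
         wavelength_nm = scans$wavelength_nm)
  }
}

#' Polarized and total bidirectional reflectance factors
#'
#' `R_Q = (R_max - R_min) / 2` estimates the specular, partially polarized
#' reflectance; `R = (R_max + R_min) / 2 = R_Q + R_min` is the total
#' bidirectional reflectance factor.
#'
#' @param R_max,R_min Extrema spectra on a common grid.
#' @return A list with spectra `R_Q` and `R`.
#' @export
compute_rq <- function(R_max, R_min) {
  if (length(R_max) != length(R_min))
    stop_dim("`R_max` and `R_min` must share one wavelength grid")
  list(R_Q = (R_max - R_min) / 2, R = (R_max + R_min) / 2)
}

#' Extract the classification features R_Qav and DIFF_R
#'
#' `R_Qav` is the unweighted mean of `R_Q` over grid points in the window
#' (500-900 nm inclusive by default), which cancels zero-mean interference
#' ripple over whole periods.  `DIFF_R` is the diffuse-spectrum ratio
#' `R_min(765) / R_min(680)` across the red edge; off-grid wavelengths are
#' linearly interpolated (no extrapolation).
#'
#' @param R_Q Polarized BRF spectrum.
#' @param R_min Diffuse (minimum) spectrum.
#' @param wavelength_nm Common wavelength grid.
#' @param window R_Qav averaging window, nm.
#' @param diff_wavelengths Numerator and denominator wavelengths of DIFF_R.
#' @return An object of class `leafpol_spectral_features`: `R_Qav`, `DIFF_R`,
#'   plus the `R_Q`, `R`, `R_min` spectra and the grid.
#' @export
#' @examples
#' wl <- seq(400, 1700, 5)
#' rq <- rep(2e-4, length(wl))
#' rmin <- 0.05 + 0.4 / (1 + exp(-(wl - 715) / 12))
#' f <- extract_features(rq, rmin, wl)
#' c(f$R_Qav, f$DIFF_R)
extract_features <- function(R_Q, R_min, wavelength_nm,
                             window = c(500, 900),
                             diff_wavelengths = c(765, 680)) {
  wl <- as.numeric(wavelength_nm)
  if (length(R_Q) != length(wl) || length(R_min) != length(wl))
    stop_dim("spectra must be on the wavelength grid")
  if (min(wl) > window[1] || max(wl) < window[2] ||
      min(wl) > min(diff_wavelengths) || max(wl) < max(diff_wavelengths))
    stop_leafpol("wavelength grid must cover the feature window and the DIFF_R wavelengths",
                 "leafpol_feature_wavelength_error")
  in_win <- wl >= window[1] & wl <= window[2]
  r_qav <- mean(R_Q[in_win])
  dv <- stats::approx(wl, R_min, xout = diff_wavelengths, rule = 1)$y
  if (!is.finite(dv[2]) || dv[2] <= 0)
    stop_leafpol(sprintf("R_min at %g nm is not positive: DIFF_R undefined",
                         diff_wavelengths[2]),
                 "leafpol_ratio_error")
  structure(list(R_Qav = r_qav, DIFF_R = dv[1] / dv[2],
                 R_Q = R_Q, R = R_Q + R_min, R_min = R_min,
                 wavelength_nm = wl, window = window,
                 diff_wavelengths = diff_wavelengths),
            class = "leafpol_spectral_features")
}

#' Full scan-set to feature pipeline
#'
#' Convenience wrapper: preprocess, select extrema, compute `R_Q`/`R`, and
#' extract `(R_Qav, DIFF_R)`.
#'
#' @inheritParams select_extrema
#' @inheritParams extract_features
#' @param preprocess Apply [preprocess_scanset()] first (default `TRUE`).
#' @return A `leafpol_spectral_features` object with the selected extrema
#'   orientations attached as `idx_min_deg` / `idx_max_deg`.
#' @export
spectral_features <- function(scans, preprocess = TRUE,
                              window = c(500, 900),
                              diff_wavelengths = c(765, 680),
                              mode = c("scan", "wavelength")) {
  if (preprocess) scans <- preprocess_scanset(scans, window)
  ex <- select_extrema(scans, window, mode)
  rq <- compute_rq(ex$R_max, ex$R_min)
  f <- extract_features(rq$R_Q, ex$R_min, scans$wavelength_nm,
                        window, diff_wavelengths)
  f$idx_min_deg <- ex$idx_min_deg
  f$idx_max_deg <- ex$idx_max_deg
  f
}

#' @export
print.leafpol_spectral_features <- function(x, ...) {
  cat(sprintf("<leafpol_spectral_features> R_Qav = %.4g, DIFF_R = %.3f\n",
              x$R_Qav, x$DIFF_R))
  invisible(x)
}

#' Brewster's angle for a refractive index
#'
#' The incidence angle at which specular reflection is maximally polarized,
#' `atan(n)`.  The measurement geometry this package assumes records
#' illumination and sensor at this angle (about 55 degrees from nadir for a
#' leaf cuticle refractive index of 1.45); it is metadata only and enters no
#' computation.
#'
#' @param n Refractive index (default 1.45).
#' @return Angle in degrees.
#' @export
#' @examples
#' brewster_angle(1.45)
brewster_angle <- function(n = 1.45) {
  check_scalar(n, "n", positive = TRUE)
  atan(n) * 180 / pi
}
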
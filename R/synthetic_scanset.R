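# Synthetic polarized scan sets with known diffuse/specular decomposition.
#
# The generator builds R(theta, lambda) = D(lambda) + S(lambda) *
# sin^2(theta - tilt) + noise, where D is a parametric green-leaf diffuse
# curve and S a flat ("white") specular term, optionally modulated by a
# thin-film interference ripple.  Ground truth (D, S) is retained so the
# Eq.-style decomposition contract R_Q = S/2, R_min = D can be tested
# exactly.

#' Parametric green-leaf diffuse reflectance curve
#'
#' Green Gaussian bump plus a logistic red edge rising to a NIR plateau over
#' a constant baseline.  Only the 500-900 nm shape and the 680/765 nm
#' contrast matter downstream; this is deliberately not a radiative-transfer
#' model.
#'
#' @param wavelength_nm Wavelength grid, nm.
#' @param base Baseline reflectance factor.
#' @param green_amplitude,green_center_nm,green_width_nm Green-peak Gaussian.
#' @param nir_plateau NIR plateau amplitude above baseline.
#' @param red_edge_nm,red_edge_width_nm Logistic red-edge position and scale.
#' @return Reflectance-factor spectrum (same length as the grid).
#' @export
diffuse_leaf_spectrum <- function(wavelength_nm, base = 0.03,
                                  green_amplitude = 0.06,
                                  green_center_nm = 550, green_width_nm = 35,
                                  nir_plateau = 0.45,
                                  red_edge_nm = 715, red_edge_width_nm = 12) {
  wl <- as.numeric(wavelength_nm)
  base + green_amplitude * exp(-(wl - green_center_nm)^2 /
                                 (2 * green_width_nm^2)) +
    nir_plateau / (1 + exp(-(wl - red_edge_nm) / red_edge_width_nm))
}

#' Specification of a synthetic polarized scan set
#'
#' @param diffuse Named list of [diffuse_leaf_spectrum()] parameters.
#' @param specular_level Flat specular reflectance-factor level `S` (>= 0).
#' @param tilt_offset_deg Surface misalignment in degrees: the modulation
#'   minimum moves to this polarizer orientation, so the 0-degree scan is not
#'   necessarily the minimum.
#' @param ripple_amplitude Relative amplitude (in `[0, 1)`) of a zero-mean
#'   thin-film interference sinusoid applied to the specular term only.
#' @param ripple_period_nm Ripple period in wavelength, nm.
#' @param noise_sd Additive Gaussian noise, reflectance-factor units.
#' @param wavelength_nm Wavelength grid; must bracket 500-900 nm and the
#'   DIFF_R wavelengths 680 and 765 nm.
#' @return An object of class `leafpol_scanset_spec`.
#' @export
scanset_spec <- function(diffuse = list(), specular_level = 5e-4,
                         tilt_offset_deg = 0, ripple_amplitude = 0,
                         ripple_period_nm = 80, noise_sd = 0,
                         wavelength_nm = seq(400, 1700, by = 5)) {
  check_scalar(specular_level, "specular_level", nonneg = TRUE)
  check_scalar(tilt_offset_deg, "tilt_offset_deg")
  check_scalar(ripple_amplitude, "ripple_amplitude", nonneg = TRUE)
  if (ripple_amplitude >= 1)
    stop_param("`ripple_amplitude` must be < 1 (specular term must stay >= 0)")
  check_scalar(ripple_period_nm, "ripple_period_nm", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  wl <- as.numeric(wavelength_nm)
  if (any(diff(wl) <= 0)) stop_param("wavelength grid must be strictly increasing")
  if (min(wl) > 500 || max(wl) < 900 || min(wl) > 680 || max(wl) < 765)
    stop_leafpol("wavelength grid must cover 500-900 nm and bracket 680 and 765 nm",
                 "leafpol_feature_wavelength_error")
  structure(list(diffuse = diffuse, specular_level = specular_level,
                 tilt_offset_deg = tilt_offset_deg,
                 ripple_amplitude = ripple_amplitude,
                 ripple_period_nm = ripple_period_nm,
                 noise_sd = noise_sd, wavelength_nm = wl),
            class = "leafpol_scanset_spec")
}

#' Generate a synthetic polarized scan set with ground truth
#'
#' @param spec A [scanset_spec()].
#' @param seed Integer seed (only the noise is random; with `noise_sd = 0`
#'   the output is fully deterministic in `spec`).
#' @return A [polarized_scanset()] with an extra `ground_truth` element:
#'   `D` (diffuse spectrum), `S` (effective specular spectrum including
#'   ripple), and `S_base` (the flat specular level).
#' @export
#' @examples
#' sc <- generate_polarized_scanset(scanset_spec(specular_level = 2e-2), seed = 1)
#' f <- spectral_features(sc)
#' f$R_Qav  # = specular_level / 2 for a flat S
generate_polarized_scanset <- function(spec, seed = 1L) {
  if (!inherits(spec, "leafpol_scanset_spec"))
    spec <- do.call(scanset_spec, as.list(spec))
  with_seed(seed, {
    wl <- spec$wavelength_nm
    D <- do.call(diffuse_leaf_spectrum, c(list(wavelength_nm = wl),
                                          spec$diffuse))
    S <- spec$specular_level *
      (1 + spec$ripple_amplitude * sin(2 * pi * (wl - 500) /
                                         spec$ripple_period_nm))
    th <- scan_orientations()
    mod <- sin((th - spec$tilt_offset_deg) * pi / 180)^2
    R <- outer(D, rep(1, length(th))) + outer(S, mod)
    if (spec$noise_sd > 0)
      R <- R + matrix(stats::rnorm(length(R), 0, spec$noise_sd),
                      nrow(R), ncol(R))
    sc <- polarized_scanset(wl, R)
    sc$ground_truth <- list(D = D, S = S, S_base = spec$specular_level,
                            tilt_offset_deg = spec$tilt_offset_deg)
    sc
  })
}

#' Simulate a labeled study of polarized scan sets
#'
#' Draws class-conditional scan-set parameters for the four phenotypes and
#' generates one scan set per sample.  Glossy surfaces get a high specular
#' level, glabrous and glaucous intermediate-to-low levels, hairy the
#' lowest; glaucous bloom and dense trichomes raise the visible diffuse
#' baseline, lowering `DIFF_R`.  Intended for end-to-end pipeline exercises;
#' the class parameterization is approximate, not a fit to real leaves.
#'
#' @param n_per_class Samples per phenotype class.
#' @param seed Master seed; each sample receives a derived sub-seed.
#' @param noise_sd Per-scan measurement noise (reflectance-factor units).
#' @return A list with `scansets` (list of `leafpol_scanset`), `labels`
#'   (factor with levels [phenotype_levels()]), and `sample_id`.
#' @export
simulate_study <- function(n_per_class = 25L, seed = 1L, noise_sd = 1e-5) {
  classes <- phenotype_levels()
  # class -> (meanlog R_Qav target, sdlog, visible baseline shift)
  pars <- list(
    glossy   = list(mlog = log(8.0e-4), slog = 0.45, base_add = 0.000),
    glaucous = list(mlog = log(2.5e-4), slog = 0.40, base_add = 0.040),
    hairy    = list(mlog = log(1.2e-4), slog = 0.35, base_add = 0.050),
    glabrous = list(mlog = log(2.0e-4), slog = 0.50, base_add = 0.000)
  )
  with_seed(seed, {
    sub_seeds <- sample.int(2147483646L, n_per_class * length(classes))
    draws <- lapply(classes, function(cl) {
      p <- pars[[cl]]
      data.frame(
        class = cl,
        s_level = 2 * stats::rlnorm(n_per_class, p$mlog, p$slog),
        base = 0.03 + p$base_add + stats::runif(n_per_class, -0.005, 0.005),
        edge_w = stats::runif(n_per_class, 10, 14),
        tilt = stats::rnorm(n_per_class, 0, 4)
      )
    })
    draws <- do.call(rbind, draws)
    scansets <- vector("list", nrow(draws))
    for (i in seq_len(nrow(draws))) {
      sp <- scanset_spec(
        diffuse = list(base = draws$base[i], red_edge_width_nm = draws$edge_w[i]),
        specular_level = draws$s_level[i],
        tilt_offset_deg = max(-15, min(15, draws$tilt[i])),
        ripple_amplitude = 0.2, noise_sd = noise_sd
      )
      scansets[[i]] <- generate_polarized_scanset(sp, seed = sub_seeds[i])
    }
    list(scansets = scansets,
         labels = factor(draws$class, levels = classes),
         sample_id = sprintf("%s_%02d", draws$class,
                             rep(seq_len(n_per_class), length(classes))))
  })
}
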
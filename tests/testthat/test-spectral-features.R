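# Spectral feature extraction: preprocessing, extrema selection, the
# polarized/total BRF identities and the (R_Qav, DIFF_R) features.

wl_full <- seq(400, 1700, by = 5)

test_that("preprocessing is the identity for zero dark and unit transmittance", {
  sc <- generate_polarized_scanset(scanset_spec(), seed = 1)
  pp <- preprocess_scanset(sc)
  expect_equal(pp$reflectance, sc$reflectance)
})

test_that("preprocessing recovers the true reflectance from raw = true * T + dark", {
  sc <- generate_polarized_scanset(scanset_spec(specular_level = 1e-3), seed = 2)
  n <- length(sc$wavelength_nm)
  dark <- 0.01 + 0.005 * sin(sc$wavelength_nm / 300)
  tr <- 0.4 + 0.2 * exp(-(sc$wavelength_nm - 900)^2 / (2 * 400^2))
  raw <- polarized_scanset(sc$wavelength_nm, sc$reflectance * tr + dark,
                           dark_reference = dark, polarizer_transmittance = tr)
  pp <- preprocess_scanset(raw)
  expect_equal(pp$reflectance, sc$reflectance, tolerance = 1e-12)
  # raw equal to dark everywhere -> all-zero reflectance
  raw0 <- polarized_scanset(sc$wavelength_nm,
                            matrix(dark, n, 19), dark_reference = dark,
                            polarizer_transmittance = tr)
  expect_true(all(preprocess_scanset(raw0)$reflectance == 0))
  # transmittance at the floor inside the window is refused
  tr_bad <- tr; tr_bad[sc$wavelength_nm == 700] <- 0
  raw_bad <- polarized_scanset(sc$wavelength_nm, sc$reflectance * tr + dark,
                               dark_reference = dark,
                               polarizer_transmittance = tr_bad)
  expect_error(preprocess_scanset(raw_bad),
               class = "leafpol_normalization_error")
})

test_that("extrema selection matches the exhaustive window-mean oracle on random scans", {
  set.seed(6)
  for (i in 1:5) {
    R <- matrix(runif(length(wl_full) * 19, 0, 0.5), ncol = 19)
    sc <- polarized_scanset(wl_full, R)
    ex <- select_extrema(sc)
    m <- apply(R[wl_full >= 500 & wl_full <= 900, ], 2, mean)
    expect_equal(ex$idx_min_deg, scan_orientations()[which.min(m)])
    expect_equal(ex$idx_max_deg, scan_orientations()[which.max(m)])
    expect_equal(ex$R_min, R[, which.min(m)])
    expect_equal(ex$R_max, R[, which.max(m)])
  }
})

test_that("all-equal scans tie-break toward 0 (min) and 90 (max) degrees", {
  sc <- polarized_scanset(wl_full, matrix(0.2, length(wl_full), 19))
  ex <- select_extrema(sc)
  expect_equal(ex$idx_min_deg, 0)
  expect_equal(ex$idx_max_deg, 90)
})

test_that("R_Q and R follow the half-difference/half-sum identities", {
  rmax <- rep(0.06, 5); rmin <- rep(0.02, 5)
  rq <- compute_rq(rmax, rmin)
  expect_equal(rq$R_Q, rep(0.02, 5))
  expect_equal(rq$R, rep(0.04, 5))
  # unpolarized limit
  rq0 <- compute_rq(rmin, rmin)
  expect_equal(rq0$R_Q, rep(0, 5))
  expect_equal(rq0$R, rmin)
  expect_error(compute_rq(rmax, rmin[1:3]), class = "leafpol_dimension_error")
})

test_that("total-reflectance conservation R = R_Q + R_min holds on every synthetic scan set", {
  set.seed(11)
  for (seed in 1:4) {
    sp <- scanset_spec(specular_level = runif(1, 0, 2e-3),
                       tilt_offset_deg = runif(1, -10, 10),
                       ripple_amplitude = runif(1, 0, 0.4),
                       noise_sd = 1e-5)
    sc <- generate_polarized_scanset(sp, seed = seed)
    f <- spectral_features(sc)
    expect_lt(max(abs(f$R - f$R_Q - f$R_min)), 1e-12)
    # whole-scan selection guarantees a nonnegative window average; the
    # per-wavelength envelope guarantees pointwise nonnegativity
    expect_gte(f$R_Qav, 0)
    fw <- spectral_features(sc, mode = "wavelength")
    expect_true(all(fw$R_Q >= 0))
  }
})

test_that("R_Qav of a constant plus whole-period sinusoid equals the constant", {
  # interference-ripple mitigation: zero-mean ripple with an integer number
  # of periods in [500, 900] cancels in the window average
  wl <- seq(400, 1700, by = 5)
  const <- 3e-4
  rq <- const + 1e-4 * sin(2 * pi * (wl - 500) / 100)  # 4 periods in window
  f <- extract_features(rq, rep(0.1, length(wl)), wl)
  expect_equal(f$R_Qav, const, tolerance = 1e-6)
})

test_that("feature arithmetic: window mean and the 765/680 diffuse ratio", {
  wl <- seq(400, 1700, by = 5)
  rq <- rep(2e-4, length(wl))
  rmin <- ifelse(wl >= 765, 0.45, 0.05)
  f <- extract_features(rq, rmin, wl)
  expect_equal(f$R_Qav, 2e-4)
  expect_equal(f$DIFF_R, 9)
  expect_error(extract_features(rq, rmin - 0.05, wl),
               class = "leafpol_ratio_error")
  expect_error(extract_features(rq[1:10], rmin[1:10], wl[1:10]),
               class = "leafpol_feature_wavelength_error")
})

test_that("R_Qav is stable under wavelength-grid refinement", {
  f_of_grid <- function(step) {
    wl <- seq(400, 1700, by = step)
    rq <- 2e-4 * (1 + 0.3 * sin(2 * pi * wl / 173))
    extract_features(rq, rep(0.1, length(wl)), wl)$R_Qav
  }
  expect_equal(f_of_grid(5), f_of_grid(1), tolerance = 1e-3)
})

test_that("features commute with positive rescaling of both extrema", {
  sc <- generate_polarized_scanset(scanset_spec(specular_level = 8e-4), seed = 3)
  ex <- select_extrema(sc)
  f1 <- extract_features(compute_rq(ex$R_max, ex$R_min)$R_Q, ex$R_min,
                         sc$wavelength_nm)
  k <- 2.7
  f2 <- extract_features(compute_rq(k * ex$R_max, k * ex$R_min)$R_Q,
                         k * ex$R_min, sc$wavelength_nm)
  expect_equal(f2$R_Qav, k * f1$R_Qav)
  expect_equal(f2$DIFF_R, f1$DIFF_R)
})

test_that("Brewster geometry metadata follows arctan of the refractive index", {
  expect_equal(brewster_angle(1.45), atan(1.45) * 180 / pi)
  expect_equal(brewster_angle(1), 45)
})
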
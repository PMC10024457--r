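# Cell morphology metrics: areas, margin undulation, cap aspect ratio,
# sample averaging and pubescence coverage.

test_that("cell size converts pixel areas to square micrometers", {
  sq <- cell_trace(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  expect_equal(cell_size(sq, pixel_scale = 9.8e-5), 1e4 * 0.098^2)  # 96.04
  tri <- cell_trace(cbind(c(0, 100, 0), c(0, 0, 100)))
  expect_equal(cell_size(tri, 9.8e-5), cell_size(sq, 9.8e-5) / 2)
})

test_that("shoelace and rasterized pixel-count areas agree within 2% on a random 12-gon", {
  set.seed(8)
  a <- sort(runif(12, 0, 2 * pi))
  r <- runif(12, 80, 150)
  v <- cbind(160 + r * cos(a), 160 + r * sin(a))
  tr <- cell_trace(v)
  s <- cell_size(tr, 1e-3, method = "shoelace")
  p <- cell_size(tr, 1e-3, method = "pixel")
  expect_lt(abs(s - p) / s, 0.02)
})

test_that("margin undulation is 1 for convex traces and matches the star oracle", {
  expect_equal(margin_undulation(cell_trace(regular_polygon(4, 10))), 1)
  expect_equal(margin_undulation(cell_trace(regular_polygon(100, 3))), 1)
  # 4-pointed star, outer 1 / inner 0.5: area 8 * (1/2 * 1 * 0.5 * sin 45) over
  # hull area 2 -> sqrt(2)/2
  star <- star_polygon(1, 0.5)
  a1 <- shoelace_oracle(star)
  hull <- star[grDevices::chull(star), ]
  a2 <- shoelace_oracle(hull)
  expect_equal(margin_undulation(cell_trace(star)), a1 / a2)
  expect_equal(margin_undulation(cell_trace(star)), sqrt(2) / 2,
               tolerance = 1e-12)
})

test_that("margin undulation is bounded by 1 and invariant to similarity transforms", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:14, 1)
    # jittered evenly spaced angles keep every angular gap < pi, so the
    # radial polygon is star-shaped about the origin and simple
    a <- 2 * pi * (seq_len(n) - 1) / n + runif(n, 0, pi / n)
    r <- runif(n, 50, 120)
    v <- cbind(r * cos(a), r * sin(a))
    mu <- margin_undulation(cell_trace(v))
    expect_gt(mu, 0)
    expect_lte(mu, 1 + 1e-12)
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.5, 3)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    v2 <- sweep(s * (v %*% rot), 2, c(17, -4), "+")
    expect_equal(margin_undulation(cell_trace(v2)), mu, tolerance = 1e-9)
  }
})

test_that("self-intersecting traces are rejected", {
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(cell_trace(bowtie), class = "leafpol_geometry_error")
  expect_error(cell_trace(cbind(c(0, 1), c(0, 1))),
               class = "leafpol_geometry_error")
})

test_that("cap aspect ratio evaluates width/height from peak and valley", {
  expect_equal(cap_ratio_from_points(c(0, 0, 0.01), c(100, 0, 0), 9.8e-5),
               1.96)
  # identical planar position -> zero width -> ratio 0
  expect_equal(cap_ratio_from_points(c(5, 5, 0.02), c(5, 5, 0.01), 9.8e-5), 0)
  expect_error(cap_ratio_from_points(c(0, 0, 0.01), c(10, 0, 0.01), 9.8e-5),
               class = "leafpol_flat_cell_error")
  # homogeneity: linear in the pixel scale, inverse in the height
  r1 <- cap_ratio_from_points(c(0, 0, 0.01), c(30, 40, 0), 9.8e-5)
  expect_equal(cap_ratio_from_points(c(0, 0, 0.01), c(30, 40, 0), 2 * 9.8e-5),
               2 * r1)
  expect_equal(cap_ratio_from_points(c(0, 0, 0.02), c(30, 40, 0), 9.8e-5),
               r1 / 2)
})

test_that("cap aspect ratio on a depth map finds the in-polygon extrema", {
  depth <- matrix(0, 40, 40)
  depth[20, 30] <- 0.01                 # peak at (x = 30, y = 20)
  depth[20, 10] <- -0.002               # valley at (x = 10, y = 20)
  tr <- cell_trace(regular_polygon(24, 18, cx = 20, cy = 20))
  res <- cap_aspect_ratio(tr, depth, pixel_scale = 1e-3)
  expect_equal(unname(res$peak), c(30, 20, 0.01))
  expect_equal(unname(res$valley), c(10, 20, -0.002))
  expect_equal(res$ratio, 2 * 1e-3 * 20 / 0.012)
  expect_error(cap_aspect_ratio(tr, matrix(0.5, 40, 40), 1e-3),
               class = "leafpol_flat_cell_error")
})

test_that("sample summary averages metrics and flags flat-cell exclusions", {
  mk <- function(size, und, cap) {
    structure(list(cell_size_um2 = size, margin_undulation = und,
                   cap_aspect_ratio = cap, valid_cap = !is.na(cap),
                   peak = NULL, valley = NULL),
              class = "leafpol_cell_metrics")
  }
  five <- lapply(1:5, function(i) mk(i, 0.9, 10))
  s <- summarize_sample(five)
  expect_equal(s$cell_size_um2, 3)
  expect_equal(s$cap_aspect_ratio, 10)
  expect_equal(s$n_tracings, 5)
  # one flat-cell failure among five: cap mean over the remaining four
  mixed <- lapply(1:5, function(i) mk(100, 0.8, if (i == 3) NA else i))
  s2 <- summarize_sample(mixed)
  expect_equal(s2$cap_aspect_ratio, mean(c(1, 2, 4, 5)))
  expect_equal(s2$n_valid_cap, 4)
  expect_true(s2$usable_flag)
  expect_error(summarize_sample(list()), class = "leafpol_summary_error")
})

test_that("pubescence coverage is the true-pixel percentage and is monotone", {
  expect_equal(pubescence_coverage(matrix(FALSE, 10, 10)), 0)
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  expect_equal(pubescence_coverage(half), 50)
  more <- half; more[1, 6] <- TRUE
  expect_gt(pubescence_coverage(more), pubescence_coverage(half))
})

test_that("count-based coverage matches the mask on identical hairs", {
  expect_equal(coverage_by_count(0, rep(50, 5), 1e4), 0)
  expect_equal(coverage_by_count(100, rep(50, 5), 1e4), 50)
  expect_error(coverage_by_count(10, rep(50, 4), 1e4),
               class = "leafpol_parameter_error")
  # grid of identical disjoint hairs: count x mean-of-5 approximation agrees
  # with direct mask coverage within 5% relative
  mask <- matrix(FALSE, 120, 120)
  area <- 0L
  for (cx in seq(10, 110, by = 20)) for (cy in seq(10, 110, by = 20)) {
    patch <- outer(seq_len(120), seq_len(120),
                   function(r, c) (r - cy)^2 + (c - cx)^2 <= 9)
    mask <- mask | patch
    area <- sum(patch)
  }
  n_hairs <- 36
  cov_mask <- pubescence_coverage(mask)
  cov_count <- coverage_by_count(n_hairs, rep(area, 5), length(mask))
  expect_lt(abs(cov_mask - cov_count) / cov_mask, 0.05)
})
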
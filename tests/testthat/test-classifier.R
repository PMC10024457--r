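# Equal-priors QDA and the Monte-Carlo split harness.

balanced_data <- function(n, seed = 1, spread = 1) {
  mus <- list(glossy = c(0, 0), glaucous = c(4, 0), hairy = c(0, 4),
              glabrous = c(4, 4))
  set.seed(seed)
  d <- do.call(rbind, lapply(names(mus), function(cl)
    data.frame(R_Qav = rnorm(n, mus[[cl]][1], spread),
               DIFF_R = rnorm(n, mus[[cl]][2], spread), label = cl)))
  d$label <- factor(d$label, levels = phenotype_levels())
  d
}

test_that("fit recovers class means and is deterministic", {
  d <- balanced_data(200, seed = 2, spread = 0.01)
  m <- fit_qda(d)
  expect_equal(m$means$glaucous, c(R_Qav = 4, DIFF_R = 0), tolerance = 0.01)
  expect_identical(fit_qda(d)$covariances, m$covariances)
})

test_that("a class with fewer than 3 samples fails with its name", {
  d <- balanced_data(10)
  d <- d[!(d$label == "hairy" & duplicated(d$label)), ]  # keep 1 hairy row
  expect_error(fit_qda(d), regexp = "hairy", class = "leafpol_fit_error")
})

test_that("prediction at a class mean under identity covariances returns that class", {
  mus <- list(a = c(0, 0), b = c(3, 1), c = c(-2, 4))
  m <- qda_model(mus, list(a = diag(2), b = diag(2), c = diag(2)),
                 feature_names = c("f1", "f2"))
  for (cl in names(mus))
    expect_equal(as.character(predict(m, rbind(mus[[cl]]))), cl)
  expect_error(predict(m, rbind(c(NA, 1))), class = "leafpol_parameter_error")
})

test_that("identity covariances reduce prediction to the nearest-class-mean rule", {
  set.seed(4)
  mus <- list(glossy = c(0, 0), glaucous = c(2, -1), hairy = c(-1, 3),
              glabrous = c(3, 3))
  m <- qda_model(mus, setNames(rep(list(diag(2)), 4), names(mus)))
  x <- matrix(rnorm(200, 1, 2), 100, 2)
  pred <- predict(m, x)
  nearest <- apply(x, 1, function(p)
    names(mus)[which.min(vapply(mus, function(mu) sum((p - mu)^2), 1))])
  expect_equal(as.character(pred), nearest)
})

test_that("forcing a pooled covariance reproduces independent linear-discriminant oracles on a grid", {
  d <- balanced_data(60, seed = 7, spread = 1.2)
  m <- fit_qda(d, pooled = TRUE)
  gx <- seq(-3, 7, length.out = 50)
  grid <- expand.grid(R_Qav = gx, DIFF_R = gx)
  pred <- predict(m, grid)

  # closed-form LDA oracle: w_k = S^-1 mu_k, b_k = -mu_k' S^-1 mu_k / 2
  classes <- levels(d$label)
  mus <- lapply(classes, function(cl)
    colMeans(d[d$label == cl, 1:2]))
  nk <- table(d$label)
  sp <- Reduce(`+`, lapply(seq_along(classes), function(i)
    (nk[i] - 1) * cov(d[d$label == classes[i], 1:2]))) / (nrow(d) - 4)
  spi <- solve(sp)
  scores <- sapply(seq_along(classes), function(i) {
    w <- spi %*% mus[[i]]
    as.matrix(grid) %*% w - 0.5 * drop(t(mus[[i]]) %*% w)
  })
  oracle <- classes[apply(scores, 1, which.max)]
  expect_equal(as.character(pred), oracle)

  # independent library oracle with equal priors
  ml <- MASS::lda(label ~ R_Qav + DIFF_R, d, prior = rep(0.25, 4))
  expect_equal(as.character(pred),
               as.character(predict(ml, grid)$class))
})

test_that("QDA predictions agree with the independent MASS oracle under equal priors", {
  d <- balanced_data(80, seed = 9, spread = 1.5)
  m <- fit_qda(d)
  grid <- expand.grid(R_Qav = seq(-3, 7, length.out = 30),
                      DIFF_R = seq(-3, 7, length.out = 30))
  mq <- MASS::qda(label ~ R_Qav + DIFF_R, d, prior = rep(0.25, 4))
  expect_equal(as.character(predict(m, grid)),
               as.character(predict(mq, grid)$class))
})

test_that("equal priors make predictions invariant to duplicating one class", {
  d <- balanced_data(200, seed = 5, spread = 1)
  d_dup <- rbind(d, d[d$label == "glossy", ])
  m1 <- fit_qda(d); m2 <- fit_qda(d_dup)
  set.seed(6)
  x <- data.frame(R_Qav = rnorm(200, 2, 2), DIFF_R = rnorm(200, 2, 2))
  expect_equal(as.character(predict(m1, x)), as.character(predict(m2, x)))
})

test_that("fitted parameters converge to generator values on untruncated clouds", {
  spec <- feature_cloud_spec(
    means = list(glossy = c(8e-4, 8), glaucous = c(2.5e-4, 5),
                 hairy = c(1.1e-4, 4.5), glabrous = c(2.3e-4, 9)),
    covariances = list(
      glossy = matrix(c(16e-8, 2e-4 * 0.8, 2e-4 * 0.8, 4), 2, 2),
      glaucous = matrix(c(1.44e-8, 0, 0, 2.25), 2, 2),
      hairy = matrix(c(0.2e-8, 1e-5, 1e-5, 2.25), 2, 2),
      glabrous = matrix(c(0.56e-8, 0, 0, 6.25), 2, 2)),
    n_per_class = 10000L, bounds = NULL, classes = phenotype_levels())
  d <- generate_feature_dataset(spec, seed = 13)
  m <- fit_qda(d)
  for (cl in phenotype_levels()) {
    expect_lt(max(abs(m$means[[cl]] - spec$means[[cl]]) /
                    abs(spec$means[[cl]])), 0.05)
    rel <- norm(m$covariances[[cl]] - spec$covariances[[cl]], "F") /
      norm(spec$covariances[[cl]], "F")
    expect_lt(rel, 0.05)
  }
})

test_that("random splits have exact sizes, partition the data and are seed-deterministic", {
  d <- generate_feature_dataset(default_feature_cloud(c(104, 110, 39, 96)),
                                seed = 1)
  expect_equal(nrow(d), 349)
  sp <- run_split(d, n_train = 150, seed = 42)
  expect_length(sp$train, 150)
  expect_length(sp$test, 199)
  expect_setequal(c(sp$train, sp$test), seq_len(349))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(run_split(d, 150, seed = 42), sp)
  expect_false(identical(run_split(d, 150, seed = 43)$train, sp$train))
  expect_true(all(phenotype_levels() %in% d$label[sp$train]))
  expect_error(run_split(d, 349, seed = 1), class = "leafpol_split_error")
})

test_that("perfectly separated classes classify at rate 1 with zero spread", {
  d <- balanced_data(30, seed = 8, spread = 0.01)
  ev <- evaluate_monte_carlo(d, n_train = 60, n_runs = 50, seed = 3)
  expect_equal(ev$aggregate$mean, 1)
  expect_equal(ev$aggregate$sd, 0)
})

test_that("confusion matrices conserve test counts and the overall rate is the trace ratio", {
  d <- balanced_data(40, seed = 10, spread = 2.5)
  ev <- evaluate_monte_carlo(d, n_train = 80, n_runs = 25, seed = 7)
  # summed over runs: row sums = summed per-class test counts, trace/total = mean of per-run rates weighted by test size (equal here)
  expect_equal(sum(ev$confusion), 25 * 80)
  expect_equal(sum(diag(ev$confusion)) / sum(ev$confusion),
               mean(ev$per_run$rate))
})

test_that("the Monte-Carlo harness is deterministic under a fixed master seed", {
  d <- balanced_data(40, seed = 12, spread = 2)
  a <- evaluate_monte_carlo(d, 80, 30, seed = 21)
  b <- evaluate_monte_carlo(d, 80, 30, seed = 21)
  expect_identical(a$per_run, b$per_run)
  expect_identical(a$confusion, b$confusion)
})

test_that("aggregate mean is stable in the number of runs on fixed data", {
  d <- generate_feature_dataset(default_feature_cloud(c(104, 110, 39, 96)),
                                seed = 3)
  ev_big <- evaluate_monte_carlo(d, 150, 2000, seed = 5)
  ev_small <- evaluate_monte_carlo(d, 150, 500, seed = 5)
  se <- ev_big$aggregate$sd / sqrt(500)
  expect_lt(abs(ev_big$aggregate$mean - ev_small$aggregate$mean), 3 * se)
})

test_that("model JSON round-trips and restores identical predictions", {
  d <- balanced_data(50, seed = 14)
  m <- fit_qda(d)
  path <- tempfile(fileext = ".json")
  write_qda_model(m, path)
  m2 <- read_qda_model(path)
  x <- data.frame(R_Qav = seq(-1, 5, length.out = 40),
                  DIFF_R = seq(5, -1, length.out = 40))
  expect_equal(as.character(predict(m, x)), as.character(predict(m2, x)))
})
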
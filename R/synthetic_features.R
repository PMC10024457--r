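# Class-conditional (R_Qav, DIFF_R) feature clouds.
#
# Defaults are calibrated to the printed phenotype ranges: glabrous R_Qav
# confined to [0.48e-4, 4.32e-4], all non-glabrous classes inside
# [0.30e-4, 19.63e-4], only glossy samples above 8e-4, and hairy R_Qav
# predominantly below 2e-4.  Truncation to those ranges is part of the
# default spec; recovery of raw Gaussian parameters is a statement about
# untruncated specs (bounds = NULL).

#' Specification of a labeled feature cloud
#'
#' @param means Named list (one per class) of length-2 mean vectors
#'   `(R_Qav, DIFF_R)`.
#' @param covariances Named list of 2x2 symmetric positive-definite
#'   covariance matrices.
#' @param n_per_class Samples per class (>= 2), recycled over classes.
#' @param bounds Named list per class with elements `rqav_min`, `rqav_max`,
#'   `diffr_min` used for rejection truncation, or `NULL` entries for no
#'   truncation.
#' @param classes Class labels; defaults to [phenotype_levels()].
#' @param seed Default seed stored on the spec.
#' @return An object of class `leafpol_feature_spec`.
#' @export
feature_cloud_spec <- function(means, covariances, n_per_class = 50L,
                               bounds = NULL, classes = names(means),
                               seed = 1L) {
  if (is.null(classes) || length(classes) < 1L)
    stop_param("feature classes must be named")
  if (!setequal(names(means), classes) || !setequal(names(covariances), classes))
    stop_param("`means` and `covariances` must be named by class")
  n_per_class <- rep_len(as.integer(n_per_class), length(classes))
  if (any(n_per_class < 2L)) stop_param("need at least 2 samples per class")
  for (cl in classes) {
    m <- means[[cl]]; s <- covariances[[cl]]
    if (length(m) != 2L || !all(is.finite(m)))
      stop_param(sprintf("mean for class '%s' must be length 2", cl))
    if (!is.matrix(s) || any(dim(s) != 2L) || max(abs(s - t(s))) > 1e-12)
      stop_param(sprintf("covariance for class '%s' must be 2x2 symmetric", cl))
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0))
      stop_param(sprintf("covariance for class '%s' is not positive-definite", cl))
  }
  structure(list(classes = classes, means = means, covariances = covariances,
                 n_per_class = stats::setNames(n_per_class, classes),
                 bounds = bounds, seed = seed),
            class = "leafpol_feature_spec")
}

#' Default four-phenotype feature cloud
#'
#' Class means, covariances and truncation bounds chosen to respect the
#' printed `R_Qav` ranges of the four phenotypes and red-edge `DIFF_R`
#' magnitudes of green leaves; approximate by construction.
#'
#' @param n_per_class Samples per class.
#' @param seed Default seed stored on the spec.
#' @return A [feature_cloud_spec()].
#' @export
default_feature_cloud <- function(n_per_class = 50L, seed = 1L) {
  cov2 <- function(s1, s2, rho = 0) {
    matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)
  }
  feature_cloud_spec(
    means = list(glossy = c(8.0e-4, 8.0), glaucous = c(2.5e-4, 5.0),
                 hairy = c(1.1e-4, 4.5), glabrous = c(2.3e-4, 9.0)),
    covariances = list(glossy = cov2(4.0e-4, 2.0, 0.2),
                       glaucous = cov2(1.2e-4, 1.5),
                       hairy = cov2(0.45e-4, 1.5, 0.3),
                       glabrous = cov2(0.75e-4, 2.5)),
    n_per_class = n_per_class,
    bounds = list(
      glossy = list(rqav_min = 0.30e-4, rqav_max = 19.63e-4, diffr_min = 0.5),
      glaucous = list(rqav_min = 0.30e-4, rqav_max = 8e-4, diffr_min = 0.5),
      hairy = list(rqav_min = 0.30e-4, rqav_max = 8e-4, diffr_min = 0.5),
      glabrous = list(rqav_min = 0.48e-4, rqav_max = 4.32e-4, diffr_min = 0.5)
    ),
    classes = phenotype_levels(), seed = seed
  )
}

#' Generate a labeled (R_Qav, DIFF_R) feature table
#'
#' Samples each class from its bivariate Gaussian, rejecting draws outside
#' the class bounds (when bounds are set).  Deterministic under a fixed
#' seed.
#'
#' @param spec A [feature_cloud_spec()]; default [default_feature_cloud()].
#' @param seed Seed; defaults to the seed stored on the spec.
#' @return A data frame with columns `R_Qav`, `DIFF_R`, `label` (factor with
#'   the spec's class order).
#' @export
#' @examples
#' head(generate_feature_dataset(default_feature_cloud(10), seed = 7))
generate_feature_dataset <- function(spec = default_feature_cloud(),
                                     seed = spec$seed) {
  if (!inherits(spec, "leafpol_feature_spec"))
    stop_param("`spec` must be a leafpol_feature_spec")
  with_seed(seed, {
    out <- lapply(spec$classes, function(cl) {
      n <- spec$n_per_class[[cl]]
      mu <- spec$means[[cl]]
      sig <- spec$covariances[[cl]]
      b <- spec$bounds[[cl]]
      acc <- matrix(numeric(0), 0, 2)
      for (iter in seq_len(1000L)) {
        x <- rmvnorm_chol(max(100L, 2L * n), mu, sig)
        if (!is.null(b)) {
          keep <- x[, 1] >= (b$rqav_min %||% -Inf) &
            x[, 1] <= (b$rqav_max %||% Inf) &
            x[, 2] >= (b$diffr_min %||% -Inf)
          x <- x[keep, , drop = FALSE]
        }
        acc <- rbind(acc, x)
        if (nrow(acc) >= n) break
      }
      if (nrow(acc) < n)
        stop_param(sprintf("rejection sampling for class '%s' starved; bounds too tight",
                           cl))
      data.frame(R_Qav = acc[seq_len(n), 1], DIFF_R = acc[seq_len(n), 2],
                 label = cl)
    })
    out <- do.call(rbind, out)
    out$label <- factor(out$label, levels = spec$classes)
    rownames(out) <- NULL
    out
  })
}
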
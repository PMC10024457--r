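# Quadratic discriminant classification of (R_Qav, DIFF_R) with equal
# priors, and the repeated random-split Monte-Carlo evaluation harness.
#
# Each class k is modeled as a bivariate Gaussian N(mu_k, Sigma_k); a point
# is assigned to the class maximizing the Gaussian log-density plus log
# prior.  Priors are equal (1/K) regardless of class frequency, so
# predictions are invariant to duplicating a class's samples.

#' Construct a QDA model from explicit parameters
#'
#' @param means Named list (one per class) of feature mean vectors.
#' @param covariances Named list of symmetric positive-definite covariance
#'   matrices.
#' @param classes Class label order (ties in prediction break toward the
#'   earlier label); defaults to `names(means)`.
#' @param priors Class priors; default equal.
#' @param feature_names Feature column names expected by `predict()`.
#' @return An object of class `leafpol_qda`.
#' @export
qda_model <- function(means, covariances, classes = names(means),
                      priors = NULL,
                      feature_names = c("R_Qav", "DIFF_R")) {
  if (is.null(classes)) stop_param("`means` must be named by class")
  k <- length(classes)
  priors <- priors %||% rep(1 / k, k)
  if (length(priors) != k || abs(sum(priors) - 1) > 1e-8)
    stop_param("priors must sum to 1 (one per class)")
  prec <- logdet <- stats::setNames(vector("list", k), classes)
  for (cl in classes) {
    s <- covariances[[cl]]
    L <- tryCatch(chol(s), error = function(e)
      stop_fit(sprintf("covariance for class '%s' is singular", cl)))
    prec[[cl]] <- chol2inv(L)
    logdet[[cl]] <- 2 * sum(log(diag(L)))
  }
  structure(list(classes = classes, means = means[classes],
                 covariances = covariances[classes],
                 precisions = prec, logdets = logdet,
                 priors = stats::setNames(priors, classes),
                 feature_names = feature_names),
            class = "leafpol_qda")
}

#' Fit a quadratic discriminant model with equal priors
#'
#' Class means are sample means and class covariances unbiased (n-1) sample
#' covariances; a small ridge `1e-8 * trace/2` is added when a covariance is
#' numerically ill-conditioned (condition number above `1e12`).  Priors are
#' equal regardless of class counts.
#'
#' @param data Data frame with the feature columns and a label column.
#' @param feature_cols Feature column names (default `R_Qav`, `DIFF_R`).
#' @param label_col Label column name.
#' @param pooled Use the pooled within-class covariance for every class
#'   (reduces QDA to LDA); default `FALSE`.
#' @return A [qda_model()].
#' @export
#' @examples
#' d <- generate_feature_dataset(default_feature_cloud(30), seed = 3)
#' m <- fit_qda(d)
#' table(predict(m, d), d$label)
fit_qda <- function(data, feature_cols = c("R_Qav", "DIFF_R"),
                    label_col = "label", pooled = FALSE) {
  if (!all(c(feature_cols, label_col) %in% names(data)))
    stop_param("`data` must contain the feature and label columns")
  lab <- data[[label_col]]
  if (!is.factor(lab)) lab <- factor(lab)
  lab <- droplevels(lab)
  classes <- levels(lab)
  x <- as.matrix(data[, feature_cols, drop = FALSE])
  if (any(!is.finite(x))) stop_param("features contain non-finite values")
  means <- covs <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    xi <- x[lab == cl, , drop = FALSE]
    if (nrow(xi) < 3L)
      stop_fit(sprintf("class '%s' has fewer than 3 samples", cl))
    means[[cl]] <- colMeans(xi)
    covs[[cl]] <- stats::cov(xi)
  }
  if (pooled) {
    n_k <- table(lab)
    sp <- Reduce(`+`, lapply(classes, function(cl)
      (n_k[[cl]] - 1) * covs[[cl]])) / (nrow(x) - length(classes))
    covs <- stats::setNames(rep(list(sp), length(classes)), classes)
  }
  for (cl in classes) {
    s <- covs[[cl]]
    if (!all(is.finite(s)) || kappa(s, exact = TRUE) > 1e12)
      covs[[cl]] <- s + diag(1e-8 * sum(diag(s)) / 2, ncol(s))
  }
  model <- tryCatch(
    qda_model(means, covs, classes, feature_names = feature_cols),
    leafpol_fit_error = function(e) stop_fit(conditionMessage(e)))
  model
}

#' Predict phenotype labels from a QDA model
#'
#' @param object A `leafpol_qda` model.
#' @param newdata Data frame containing the model's feature columns, or a
#'   numeric matrix/vector of feature values.
#' @param type `"class"` (factor of labels) or `"scores"` (matrix of
#'   per-class discriminant scores: log-density + log prior).
#' @param ... Unused.
#' @return Factor of predicted labels, or the score matrix.
#' @export
predict.leafpol_qda <- function(object, newdata, type = c("class", "scores"),
                                ...) {
  type <- match.arg(type)
  x <- if (is.data.frame(newdata)) {
    if (!all(object$feature_names %in% names(newdata)))
      stop_param("`newdata` lacks the model's feature columns")
    as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else {
    m <- rbind(newdata)
    if (is.null(dim(m)) || ncol(m) != length(object$means[[1]]))
      stop_dim("`newdata` has the wrong feature dimension")
    m
  }
  if (any(!is.finite(x))) stop_param("`newdata` contains non-finite values")
  scores <- vapply(object$classes, function(cl) {
    d <- sweep(x, 2L, object$means[[cl]])
    mah <- rowSums((d %*% object$precisions[[cl]]) * d)
    -0.5 * object$logdets[[cl]] - 0.5 * mah + log(object$priors[[cl]])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(NULL, object$classes))
  if (type == "scores") return(scores)
  idx <- apply(scores, 1L, which.max)  # ties -> earliest class in order
  factor(object$classes[idx], levels = object$classes)
}

#' @export
print.leafpol_qda <- function(x, ...) {
  cat(sprintf("<leafpol_qda> %d classes (%s), features: %s, equal priors\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Random train/test partition with class-presence retry
#'
#' Uniform random partition without replacement into `n_train` training and
#' `n - n_train` testing rows.  If a class is missing from the training
#' side, the split is redrawn (up to `max_retries` times); the number of
#' redraws is recorded as an attribute.
#'
#' @param data Labeled data frame.
#' @param n_train Training set size (< `nrow(data)`).
#' @param seed Seed making the partition deterministic.
#' @param label_col Label column name.
#' @param max_retries Maximum redraws before failing.
#' @return List with integer vectors `train` and `test`.
#' @export
run_split <- function(data, n_train, seed, label_col = "label",
                      max_retries = 100L) {
  n <- nrow(data)
  if (n_train >= n || n_train < 1L)
    stop_leafpol("`n_train` must be in [1, nrow(data) - 1]",
                 "leafpol_split_error")
  lab <- factor(data[[label_col]])
  out <- with_seed(seed, {
    res <- NULL
    for (retry in 0:max_retries) {
      tr <- sort(sample.int(n, n_train))
      if (all(levels(lab) %in% lab[tr])) {
        res <- list(train = tr, test = setdiff(seq_len(n), tr))
        attr(res, "retries") <- retry
        break
      }
    }
    res
  })
  if (is.null(out))
    stop_leafpol("could not draw a split containing every class in training",
                 "leafpol_split_error")
  out
}

#' Monte-Carlo random-split evaluation of the QDA classifier
#'
#' Repeats: split the data at random into training and testing sets, fit
#' the equal-priors QDA on the training set, classify the test set, and
#' record the overall and per-class correct classification rates and the
#' confusion matrix.  Aggregates mean, SD, min and max over runs.  A master
#' seed spawns one sub-seed per run, so any single run is independently
#' reproducible.
#'
#' @param data Labeled feature data frame.
#' @param n_train Training set size per run.
#' @param n_runs Number of Monte-Carlo runs (>= 1).
#' @param seed Master seed.
#' @param feature_cols,label_col Column names.
#' @return An object of class `leafpol_eval`: `per_run` (data frame with one
#'   row per run: seed, overall rate, per-class rates), `confusion` (summed
#'   confusion matrix, rows = truth), `aggregate` (overall mean/sd/min/max
#'   and per-class mean/sd), `n_skipped`, plus the evaluation settings.
#' @export
evaluate_monte_carlo <- function(data, n_train, n_runs, seed,
                                 feature_cols = c("R_Qav", "DIFF_R"),
                                 label_col = "label") {
  if (n_runs < 1L) stop_param("`n_runs` must be >= 1")
  lab <- factor(data[[label_col]])
  classes <- levels(lab)
  run_seeds <- with_seed(seed, sample.int(2147483646L, n_runs))
  k <- length(classes)
  rates <- numeric(n_runs)
  class_rates <- matrix(NA_real_, n_runs, k, dimnames = list(NULL, classes))
  conf_total <- matrix(0L, k, k, dimnames = list(truth = classes,
                                                 predicted = classes))
  skipped <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    sp <- run_split(data, n_train, run_seeds[i], label_col)
    fit <- tryCatch(fit_qda(data[sp$train, , drop = FALSE], feature_cols,
                            label_col),
                    leafpol_fit_error = function(e) NULL)
    if (is.null(fit)) { skipped[i] <- TRUE; next }
    truth <- factor(lab[sp$test], levels = classes)
    pred <- predict(fit, data[sp$test, , drop = FALSE])
    pred <- factor(as.character(pred), levels = classes)
    cm <- table(truth, pred)
    conf_total <- conf_total + cm
    rates[i] <- sum(diag(cm)) / length(truth)
    rs <- rowSums(cm)
    class_rates[i, ] <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  }
  if (sum(skipped) > 0.01 * n_runs)
    stop_leafpol(sprintf("%d of %d runs skipped (fit failures)",
                         sum(skipped), n_runs),
                 "leafpol_evaluation_error")
  keep <- !skipped
  per_run <- data.frame(run = seq_len(n_runs)[keep], seed = run_seeds[keep],
                        rate = rates[keep])
  for (cl in classes) per_run[[paste0("rate_", cl)]] <- class_rates[keep, cl]
  structure(list(
    per_run = per_run,
    confusion = conf_total,
    aggregate = list(
      mean = mean(per_run$rate), sd = stats::sd(per_run$rate),
      min = min(per_run$rate), max = max(per_run$rate),
      class_mean = colMeans(class_rates[keep, , drop = FALSE], na.rm = TRUE),
      class_sd = apply(class_rates[keep, , drop = FALSE], 2L, stats::sd,
                       na.rm = TRUE)
    ),
    n_skipped = sum(skipped), n_train = n_train, n_runs = n_runs,
    seed = seed, classes = classes
  ), class = "leafpol_eval")
}

#' @export
print.leafpol_eval <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<leafpol_eval> %d runs (train %d / test %d)\n",
              x$n_runs, x$n_train, sum(x$confusion) / max(1, nrow(x$per_run))))
  cat(sprintf("  overall rate: mean %.1f%% (sd %.1f), min %.1f%%, max %.1f%%\n",
              100 * a$mean, 100 * a$sd, 100 * a$min, 100 * a$max))
  for (cl in x$classes)
    cat(sprintf("  %-9s mean %.1f%% (sd %.1f)\n", paste0(cl, ":"),
                100 * a$class_mean[[cl]], 100 * a$class_sd[[cl]]))
  invisible(x)
}
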
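# Pipeline configuration and end-to-end composition:
# stacks -> reconstruction -> morphology metrics (when stacks are present),
# scan sets -> spectral features -> QDA fit -> Monte-Carlo evaluation.

#' Pipeline configuration
#'
#' Bundles the physical and procedural settings of a full analysis.  All
#' physical quantities must be positive; the configuration round-trips
#' losslessly through JSON ([write_config()] / [read_config()]).
#'
#' @param magnification 100 or 500.
#' @param pixel_scale mm/pixel (default the 500x calibration `9.8e-5`; the
#'   100x scale must be supplied by the user).
#' @param stage_step_mm Stage step in mm (0.005 at 100x, 0.001 at 500x).
#' @param filter_depth,filter_composite Post-filter targets for
#'   [stack_focus()].
#' @param feature_window R_Qav averaging window, nm.
#' @param diff_wavelengths DIFF_R numerator and denominator wavelengths, nm.
#' @param n_train Training set size per Monte-Carlo run.
#' @param n_runs Number of Monte-Carlo runs.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return An object of class `leafpol_config`.
#' @export
pipeline_config <- function(magnification = 500,
                            pixel_scale = 9.8e-5,
                            stage_step_mm = if (magnification == 500) 0.001 else 0.005,
                            filter_depth = TRUE, filter_composite = FALSE,
                            feature_window = c(500, 900),
                            diff_wavelengths = c(765, 680),
                            n_train = 150L, n_runs = 10000L, seed = 1L,
                            out_dir = ".") {
  if (!magnification %in% c(100, 500))
    stop_param("`magnification` must be 100 or 500")
  check_scalar(pixel_scale, "pixel_scale", positive = TRUE)
  check_scalar(stage_step_mm, "stage_step_mm", positive = TRUE)
  if (length(feature_window) != 2L || feature_window[1] >= feature_window[2])
    stop_param("`feature_window` must be an increasing (lo, hi) pair")
  if (length(diff_wavelengths) != 2L || any(diff_wavelengths <= 0))
    stop_param("`diff_wavelengths` must be two positive wavelengths")
  check_scalar(n_train, "n_train", positive = TRUE)
  check_scalar(n_runs, "n_runs", positive = TRUE)
  structure(list(magnification = magnification, pixel_scale = pixel_scale,
                 stage_step_mm = stage_step_mm,
                 filter_depth = isTRUE(filter_depth),
                 filter_composite = isTRUE(filter_composite),
                 feature_window = as.numeric(feature_window),
                 diff_wavelengths = as.numeric(diff_wavelengths),
                 n_train = as.integer(n_train), n_runs = as.integer(n_runs),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "leafpol_config")
}

#' @rdname pipeline_config
#' @param config A `leafpol_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

#' Run the analysis pipeline on a batch of samples
#'
#' For each sample with a scan set: extract `(R_Qav, DIFF_R)`.  When labels
#' are supplied and every class has at least 3 samples, fit the equal-priors
#' QDA and run the Monte-Carlo split evaluation.  When focus stacks are
#' supplied, reconstruct each and (with traces) compute morphology metrics.
#' A failing sample is reported and skipped; the pipeline errors only if
#' every sample fails.  Outputs (`features.csv`, `model.json`,
#' `evaluation.json`, `runs.csv`) are written under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param scansets List of [polarized_scanset()] objects (or `NULL`).
#' @param labels Optional factor/character vector of phenotype labels, one
#'   per scan set.
#' @param sample_id Optional sample identifiers.
#' @param stacks Optional list of [focus_stack()] objects.
#' @param traces Optional list (one per stack) of lists of [cell_trace()]s.
#' @return A list with `features` (data frame), `model` (`leafpol_qda` or
#'   `NULL`), `evaluation` (`leafpol_eval` or `NULL`), `reconstructions`,
#'   `metrics`, and the paths written.
#' @export
run_pipeline <- function(config, scansets = NULL, labels = NULL,
                         sample_id = NULL, stacks = NULL, traces = NULL) {
  if (!inherits(config, "leafpol_config"))
    stop_param("`config` must be a leafpol_config")
  if (is.null(scansets) && is.null(stacks))
    stop_param("at least one of `scansets` or `stacks` is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  features <- NULL
  model <- evaluation <- NULL
  if (!is.null(scansets)) {
    n <- length(scansets)
    sample_id <- sample_id %||% sprintf("sample_%03d", seq_len(n))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rows[[i]] <- tryCatch({
        f <- spectral_features(scansets[[i]],
                               window = config$feature_window,
                               diff_wavelengths = config$diff_wavelengths)
        data.frame(sample_id = sample_id[i], R_Qav = f$R_Qav,
                   DIFF_R = f$DIFF_R, min_idx_deg = f$idx_min_deg,
                   max_idx_deg = f$idx_max_deg)
      }, leafpol_error = function(e) {
        message(sprintf("sample %s failed: %s", sample_id[i],
                        conditionMessage(e)))
        NULL
      })
    }
    ok <- !vapply(rows, is.null, logical(1))
    if (!any(ok)) stop_leafpol("all samples failed feature extraction",
                               "leafpol_evaluation_error")
    features <- do.call(rbind, rows[ok])
    if (!is.null(labels)) {
      lev <- if (all(unique(as.character(labels)) %in% phenotype_levels()))
        phenotype_levels() else sort(unique(as.character(labels)))
      features$label <- factor(as.character(labels)[ok], levels = lev)
    }
    fpath <- file.path(config$out_dir, "features.csv")
    write_features_csv(features, fpath)
    paths <- c(paths, fpath)

    if (!is.null(labels) && all(table(features$label) >= 3)) {
      model <- fit_qda(features)
      mpath <- file.path(config$out_dir, "model.json")
      write_qda_model(model, mpath)
      evaluation <- evaluate_monte_carlo(features, n_train = config$n_train,
                                         n_runs = config$n_runs,
                                         seed = config$seed)
      epath <- file.path(config$out_dir, "evaluation.json")
      jsonlite::write_json(list(
        n_train = evaluation$n_train, n_runs = evaluation$n_runs,
        seed = evaluation$seed,
        mean = evaluation$aggregate$mean, sd = evaluation$aggregate$sd,
        min = evaluation$aggregate$min, max = evaluation$aggregate$max,
        class_mean = as.list(evaluation$aggregate$class_mean),
        class_sd = as.list(evaluation$aggregate$class_sd)
      ), epath, auto_unbox = TRUE, digits = NA)
      rpath <- file.path(config$out_dir, "runs.csv")
      utils::write.csv(evaluation$per_run, rpath, row.names = FALSE)
      paths <- c(paths, mpath, epath, rpath)
    }
  }

  recons <- metrics <- NULL
  if (!is.null(stacks)) {
    recons <- vector("list", length(stacks))
    metrics <- vector("list", length(stacks))
    for (i in seq_along(stacks)) {
      recons[[i]] <- tryCatch(
        stack_focus(stacks[[i]], pixel_scale = config$pixel_scale,
                    filter_depth = config$filter_depth,
                    filter_composite = config$filter_composite),
        leafpol_error = function(e) {
          message(sprintf("stack %d failed: %s", i, conditionMessage(e)))
          NULL
        })
      if (!is.null(recons[[i]]) && !is.null(traces) && !is.null(traces[[i]])) {
        cm <- lapply(traces[[i]], cell_metrics,
                     depth_mm = recons[[i]]$depth_mm,
                     pixel_scale = config$pixel_scale)
        metrics[[i]] <- summarize_sample(cm)
      }
    }
    if (all(vapply(recons, is.null, logical(1))))
      stop_leafpol("all stacks failed reconstruction",
                   "leafpol_evaluation_error")
  }

  invisible(list(features = features, model = model, evaluation = evaluation,
                 reconstructions = recons, metrics = metrics, paths = paths))
}
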
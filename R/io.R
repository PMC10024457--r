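# Readers and writers for the on-disk formats: multi-page TIFF focus stacks
# with JSON stage manifests, scan-set / reference CSVs, feature tables,
# serialized QDA models, depth/composite TIFFs and mask PNGs.
#
# CSV dialect: comma-separated, '.' decimal, UTF-8, mandatory header row.
# Depth maps are stored as 32-bit float TIFF in mm; composites as 16-bit.

#' Write a focus stack as multi-page TIFF plus a JSON stage manifest
#'
#' @param stack A [focus_stack()].
#' @param image_path Output TIFF path (one page per slice).
#' @param manifest_path Output JSON manifest path; records `start_mm`,
#'   `step_mm`, `n`.
#' @return Invisibly, the two paths.
#' @export
write_focus_stack <- function(stack, image_path, manifest_path) {
  if (!inherits(stack, "leafpol_stack")) stop_format("`stack` must be a leafpol_stack")
  imgs <- lapply(stack$images, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(imgs, image_path, bits.per.sample = 32L)
  manifest <- list(start_mm = stack$stage_heights[1],
                   step_mm = diff(stack$stage_heights)[1],
                   n = length(stack$images))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image_path, manifest_path))
}

rgb_to_luma <- function(a) {
  if (length(dim(a)) == 3L)
    0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
  else a
}

#' Read a focus stack from TIFF(s) and a JSON stage manifest
#'
#' Accepts either a multi-page TIFF or a directory of single-page images.
#' The manifest must provide `start_mm`, `step_mm` and `n`; an optional
#' `files` array fixes the slice order for directory input (otherwise files
#' are taken in lexical order).  RGB slices are converted to luma; values
#' are floats in `[0, 1]`.
#'
#' @param path Multi-page TIFF file or directory of TIFF/PNG slices.
#' @param manifest_path JSON manifest path.
#' @return A [focus_stack()] ordered by ascending stage height.
#' @export
read_focus_stack <- function(path, manifest_path) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (key in c("start_mm", "step_mm", "n"))
    if (is.null(manifest[[key]]))
      stop_format(sprintf("manifest %s is missing key '%s'", manifest_path, key))
  n <- as.integer(manifest$n)
  if (dir.exists(path)) {
    files <- manifest$files %||%
      sort(list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE))
    files <- file.path(path, files)
    if (length(files) != n)
      stop_format(sprintf("manifest n = %d but %d image files found in %s",
                          n, length(files), path))
    imgs <- lapply(files, function(f) {
      a <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
      rgb_to_luma(a)
    })
  } else {
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    if (length(imgs) != n)
      stop_format(sprintf("manifest n = %d but %d pages found in %s",
                          n, length(imgs), path))
    imgs <- lapply(imgs, rgb_to_luma)
  }
  heights <- manifest$start_mm + (seq_len(n) - 1L) * manifest$step_mm
  focus_stack(imgs, heights)
}

#' Write a scan set (and its reference spectra) as CSV
#'
#' Column 1 is `wavelength_nm`; columns 2-20 are labeled `deg_0` .. `deg_90`
#' by polarizer orientation.
#'
#' @param scans A [polarized_scanset()].
#' @param path Output CSV path.
#' @param dark_path,transmittance_path Optional paths for the reference
#'   spectra (`wavelength_nm`, `value` columns).
#' @return Invisibly, `path`.
#' @export
write_scanset <- function(scans, path, dark_path = NULL,
                          transmittance_path = NULL) {
  if (!inherits(scans, "leafpol_scanset"))
    stop_format("`scans` must be a leafpol_scanset")
  df <- data.frame(wavelength_nm = scans$wavelength_nm, scans$reflectance)
  names(df)[-1] <- paste0("deg_", scans$orientations_deg)
  utils::write.csv(df, path, row.names = FALSE)
  ref <- function(v, p) {
    utils::write.csv(data.frame(wavelength_nm = scans$wavelength_nm,
                                value = v), p, row.names = FALSE)
  }
  if (!is.null(dark_path)) ref(scans$dark_reference, dark_path)
  if (!is.null(transmittance_path))
    ref(scans$polarizer_transmittance, transmittance_path)
  invisible(path)
}

read_reference_spectrum <- function(path, grid) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop_format(sprintf("%s must have columns wavelength_nm, value", path))
  if (isTRUE(all.equal(df$wavelength_nm, grid))) return(df$value)
  warning(sprintf("interpolating %s onto the scan wavelength grid", path))
  stats::approx(df$wavelength_nm, df$value, xout = grid, rule = 1)$y
}

#' Read a polarized scan set from CSV
#'
#' Verifies that the orientation columns cover 0..90 degrees in 5-degree
#' steps (any order; columns are internally reordered) and attaches optional
#' dark-reference and polarizer-transmittance spectra, interpolated onto the
#' scan grid with a warning if their grids differ.
#'
#' @param path Scan CSV (column 1 `wavelength_nm`, 19 orientation columns
#'   labeled by degrees, e.g. `deg_45` or `45`).
#' @param dark_path,transmittance_path Optional reference CSVs.
#' @return A [polarized_scanset()].
#' @export
read_scanset <- function(path, dark_path = NULL, transmittance_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df))
    stop_format(sprintf("%s lacks a wavelength_nm column", path))
  ocols <- setdiff(names(df), "wavelength_nm")
  deg <- suppressWarnings(as.numeric(sub("^(deg[_ ]?|X)", "", ocols)))
  if (any(is.na(deg)))
    stop_format(sprintf("cannot parse orientation columns: %s",
                        paste(ocols[is.na(deg)], collapse = ", ")))
  want <- scan_orientations()
  missing <- setdiff(want, deg)
  if (length(missing) > 0 || length(deg) != length(want))
    stop_format(sprintf("scan CSV must have orientations %s; missing: %s; found: %s",
                        "0..90 by 5",
                        paste(missing, collapse = ", "),
                        paste(sort(deg), collapse = ", ")))
  ord <- order(deg)
  grid <- df$wavelength_nm
  refl <- as.matrix(df[, ocols[ord], drop = FALSE])
  dark <- if (!is.null(dark_path)) read_reference_spectrum(dark_path, grid)
  tr <- if (!is.null(transmittance_path))
    read_reference_spectrum(transmittance_path, grid)
  polarized_scanset(grid, refl, dark_reference = dark,
                    polarizer_transmittance = tr)
}

#' Write / read a per-sample feature table as CSV
#'
#' Mandatory columns `R_Qav`, `DIFF_R`, `label`; extra columns (sample ids,
#' selected orientations) are preserved.
#'
#' @param features Data frame of features.
#' @param path CSV path.
#' @return `write_features_csv()` invisibly returns `path`;
#'   `read_features_csv()` returns the data frame with `label` as a factor
#'   (levels in [phenotype_levels()] order when applicable).
#' @export
write_features_csv <- function(features, path) {
  if (!all(c("R_Qav", "DIFF_R") %in% names(features)))
    stop_format("feature table must have columns R_Qav and DIFF_R")
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("R_Qav", "DIFF_R") %in% names(df)))
    stop_format(sprintf("%s lacks R_Qav/DIFF_R columns", path))
  if ("label" %in% names(df)) {
    lev <- if (all(unique(df$label) %in% phenotype_levels()))
      phenotype_levels() else sort(unique(df$label))
    df$label <- factor(df$label, levels = lev)
  }
  df
}

#' Serialize / restore a QDA model as JSON
#'
#' @param model A `leafpol_qda`.
#' @param path JSON path.
#' @return `write_qda_model()` invisibly returns `path`; `read_qda_model()`
#'   returns the restored [qda_model()].
#' @export
write_qda_model <- function(model, path) {
  if (!inherits(model, "leafpol_qda")) stop_format("`model` must be a leafpol_qda")
  obj <- list(classes = model$classes,
              feature_names = model$feature_names,
              priors = as.numeric(model$priors),
              means = model$means,
              covariances = lapply(model$covariances, function(m)
                as.numeric(m)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qda_model
#' @export
read_qda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  classes <- obj$classes
  means <- stats::setNames(lapply(classes, function(cl)
    as.numeric(obj$means[[cl]])), classes)
  covs <- stats::setNames(lapply(classes, function(cl)
    matrix(as.numeric(obj$covariances[[cl]]), 2, 2)), classes)
  qda_model(means, covs, classes, priors = obj$priors,
            feature_names = obj$feature_names)
}

#' Write a depth map or composite image as TIFF
#'
#' Depth maps are stored as 32-bit float TIFF in mm (stage heights of
#' microscope stacks are well inside the `[0, 1]` storage range); composites
#' as 16-bit.
#'
#' @param m Matrix to write.
#' @param path Output TIFF path.
#' @param what `"depth"` (float) or `"composite"` (16-bit).
#' @return Invisibly, `path`.
#' @export
write_map_tiff <- function(m, path, what = c("depth", "composite")) {
  what <- match.arg(what)
  bits <- if (what == "depth") 32L else 16L
  tiff::writeTIFF(pmin(pmax(m, 0), 1), path, bits.per.sample = bits)
  invisible(path)
}

#' Read / write a binary mask as PNG
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `write_mask_png()` invisibly returns `path`; `read_mask_png()`
#'   returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  rgb_to_luma(png::readPNG(path)) > 0.5
}
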
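# Shape-from-focus reconstruction.
#
# A focus stack is an ordered series of images of the same field taken at
# different microscope stage heights (0.005 mm steps at 100x, 0.001 mm at
# 500x).  Per pixel, the slice with the highest gradient magnitude is taken
# to be in focus; its stage height becomes the depth estimate.  The raw
# (quantized) depth map is then smoothed with a 10x10 median filter followed
# by a 15x15 Gaussian filter to suppress selection noise and capture the
# shape of single cells.

#' Construct a focus stack
#'
#' @param images List of numeric matrices (one per slice), all the same
#'   shape, values typically in `[0, 1]`.
#' @param stage_heights Numeric vector of stage heights in mm, one per image,
#'   strictly monotone with constant spacing (within tolerance).
#'
#' @return An object of class `leafpol_stack`.
#' @export
focus_stack <- function(images, stage_heights) {
  if (!is.list(images) || length(images) < 2L)
    stop_dim("a focus stack needs at least 2 images")
  if (!all(vapply(images, is.matrix, logical(1))))
    stop_dim("all stack images must be matrices")
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_dim("all stack images must share one shape")
  if (length(stage_heights) != length(images))
    stop_dim("need one stage height per image")
  dz <- diff(stage_heights)
  if (any(dz <= 0) && any(dz >= 0))
    stop_param("stage heights must be strictly monotone")
  if (max(abs(dz)) - min(abs(dz)) > 1e-9 + 1e-6 * max(abs(dz)))
    stop_param("stage spacing must be constant")
  if (dz[1] < 0) {  # normalize to ascending order
    images <- rev(images)
    stage_heights <- rev(stage_heights)
  }
  structure(list(images = images, stage_heights = as.numeric(stage_heights)),
            class = "leafpol_stack")
}

#' @export
print.leafpol_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<leafpol_stack> %d slices of %d x %d, stage %.4f..%.4f mm (step %.4g mm)\n",
              length(x$images), d[1], d[2],
              min(x$stage_heights), max(x$stage_heights),
              diff(x$stage_heights)[1]))
  invisible(x)
}

#' Generate a synthetic focus stack over a known surface
#'
#' Simulates the through-focus image series of a microscope: slice `i` is
#' the surface texture blurred per pixel with a Gaussian kernel of
#' `sigma = blur_coefficient * |stage_height_i - height(pixel)|` (the defocus
#' grows linearly with the stage offset from the true surface).  The
#' ground-truth best-focus index per pixel (nearest stage height) is retained
#' on the result for recovery tests.
#'
#' @param surface A `leafpol_surface` from [generate_surface()], or a height
#'   matrix in mm (then `texture` must be given).
#' @param texture Texture matrix (same shape as the height field); ignored
#'   when `surface` is a `leafpol_surface`.
#' @param stage_start_mm Stage height of the first slice, mm.
#' @param stage_step_mm Stage step between slices, mm (> 0); 0.005 at 100x
#'   magnification, 0.001 at 500x.
#' @param n_images Number of slices (>= 2).
#' @param blur_coefficient Defocus blur growth rate, pixels of Gaussian sigma
#'   per mm of stage offset.  `0` disables defocus entirely.
#'
#' @return A `leafpol_stack` with an extra `ground_truth` element
#'   (`height_mm` and `focus_index`).
#' @export
generate_focus_stack <- function(surface, texture = NULL,
                                 stage_start_mm = 0,
                                 stage_step_mm = 0.001,
                                 n_images = 30L,
                                 blur_coefficient = 600) {
  if (inherits(surface, "leafpol_surface")) {
    height <- surface$height_mm
    texture <- surface$texture
  } else {
    height <- surface
  }
  if (!is.matrix(height) || is.null(texture) || !is.matrix(texture))
    stop_dim("need a height matrix and a texture matrix")
  if (!identical(dim(height), dim(texture)))
    stop_dim("height field and texture shapes differ")
  if (n_images < 2L) stop_param("`n_images` must be >= 2")
  check_scalar(stage_step_mm, "stage_step_mm", positive = TRUE)
  check_scalar(blur_coefficient, "blur_coefficient", nonneg = TRUE)

  heights <- stage_start_mm + (seq_len(n_images) - 1L) * stage_step_mm
  npx <- length(height)

  # Quantize the per-pixel sigma field into a small set of levels and blur
  # the texture once per level; per-pixel nearest-level lookup assembles the
  # slice.  Level 0 is the identity, so blur_coefficient = 0 returns the
  # texture verbatim.
  sig_max <- blur_coefficient * max(abs(outer(heights, as.vector(height), "-")))
  if (sig_max > 0) {
    # level spacing at most half the per-step sigma increment, so adjacent
    # slices never collapse onto one blur level near focus
    n_lev <- min(96L, max(16L, 2L * ceiling(sig_max /
                                              (blur_coefficient * stage_step_mm)) + 1L))
    lev <- seq(0, sig_max, length.out = n_lev)
    blurred <- vapply(lev, function(s) as.vector(blur_gaussian(texture, s)),
                      numeric(npx))
    step_lev <- lev[2] - lev[1]
  }
  images <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    if (sig_max == 0) {
      images[[i]] <- texture
    } else {
      sig <- blur_coefficient * abs(heights[i] - height)
      li <- clamp_index(as.integer(round(sig / step_lev)) + 1L, ncol(blurred))
      images[[i]] <- matrix(blurred[cbind(seq_len(npx), as.vector(li))],
                            nrow(texture), ncol(texture))
    }
  }
  st <- focus_stack(images, heights)
  # nearest stage height per pixel (half-step ties round toward the higher
  # stage)
  gi <- clamp_index(as.integer(floor((height - stage_start_mm) /
                                       stage_step_mm + 0.5)) + 1L, n_images)
  st$ground_truth <- list(height_mm = height,
                          focus_index = matrix(gi, nrow(height), ncol(height)))
  st
}

#' Per-pixel gradient-magnitude sharpness of an image
#'
#' Central differences in the interior, forward/backward differences at the
#' borders; the sharpness is the L2 magnitude of the two components.  A
#' constant image maps to an all-zero sharpness map.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return Nonnegative matrix of the same shape.
#' @export
sharpness_map <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3L || ncol(image) < 3L)
    stop_dim("`image` must be a matrix of at least 3 x 3")
  nr <- nrow(image); nc <- ncol(image)
  gy <- (image[clamp_index(seq_len(nr) + 1L, nr), ] -
           image[clamp_index(seq_len(nr) - 1L, nr), ])
  gy[2:(nr - 1L), ] <- gy[2:(nr - 1L), ] / 2  # central in the interior
  gx <- (image[, clamp_index(seq_len(nc) + 1L, nc)] -
           image[, clamp_index(seq_len(nc) - 1L, nc)])
  gx[, 2:(nc - 1L)] <- gx[, 2:(nc - 1L)] / 2
  sqrt(gx^2 + gy^2)
}

#' Focus-stack a series into a composite image and depth map
#'
#' Per pixel, the slice with the highest [sharpness_map()] value is selected
#' (ties go to the lowest slice index).  The composite takes that slice's
#' intensity, the raw depth map takes its stage height, and the focus index
#' records the selection.  The depth map is then post-filtered with a 10x10
#' median filter and a 15x15 Gaussian filter (`sigma = 2.5`); filtering of
#' the composite is available behind `filter_composite`.
#'
#' @param stack A [focus_stack()].
#' @param pixel_scale Pixel scale metadata, mm/pixel (default the 500x
#'   calibration `9.8e-5`).
#' @param filter_depth Apply the median+Gaussian filters to the depth map
#'   (default `TRUE`).  With `FALSE`, `depth_mm` equals `depth_raw_mm`.
#' @param filter_composite Also filter the composite image (default `FALSE`).
#' @param median_size,gaussian_size,gaussian_sigma Filter parameters.
#'
#' @return An object of class `leafpol_recon` with elements `composite`,
#'   `focus_index`, `depth_mm` (post-filtered), `depth_raw_mm` (always a
#'   member of `stage_heights` per pixel), `stage_heights`, `pixel_scale`.
#' @export
#' @examples
#' surf <- generate_surface(surface_spec(field_size = 48, pixel_scale = 1e-3,
#'                                       cell_pitch_um = 24), seed = 2)
#' st <- generate_focus_stack(surf, n_images = 12)
#' rec <- stack_focus(st, pixel_scale = 1e-3)
#' range(rec$depth_raw_mm)
stack_focus <- function(stack, pixel_scale = 9.8e-5,
                        filter_depth = TRUE, filter_composite = FALSE,
                        median_size = 10L, gaussian_size = 15L,
                        gaussian_sigma = gaussian_size / 6) {
  if (!inherits(stack, "leafpol_stack")) stop_dim("`stack` must be a leafpol_stack")
  check_scalar(pixel_scale, "pixel_scale", positive = TRUE)
  n <- length(stack$images)
  best_s <- sharpness_map(stack$images[[1]])
  idx <- matrix(1L, nrow(best_s), ncol(best_s))
  for (i in 2:n) {
    s <- sharpness_map(stack$images[[i]])
    upd <- s > best_s          # strict: ties keep the lowest index
    best_s[upd] <- s[upd]
    idx[upd] <- i
  }
  npx <- length(idx)
  imgmat <- vapply(stack$images, as.vector, numeric(npx))
  composite <- matrix(imgmat[cbind(seq_len(npx), as.vector(idx))],
                      nrow(idx), ncol(idx))
  depth_raw <- matrix(stack$stage_heights[idx], nrow(idx), ncol(idx))
  depth <- depth_raw
  if (filter_depth) {
    depth <- median_filter(depth, median_size)
    depth <- gaussian_filter(depth, gaussian_size, gaussian_sigma)
  }
  if (filter_composite) {
    composite <- median_filter(composite, median_size)
    composite <- gaussian_filter(composite, gaussian_size, gaussian_sigma)
  }
  structure(list(composite = composite, focus_index = idx,
                 depth_mm = depth, depth_raw_mm = depth_raw,
                 stage_heights = stack$stage_heights,
                 pixel_scale = pixel_scale),
            class = "leafpol_recon")
}

#' @export
print.leafpol_recon <- function(x, ...) {
  cat(sprintf("<leafpol_recon> %d x %d, depth %.4f..%.4f mm, pixel scale %g mm/px\n",
              nrow(x$depth_mm), ncol(x$depth_mm),
              min(x$depth_mm), max(x$depth_mm), x$pixel_scale))
  invisible(x)
}

#' Map a reconstruction to 3-D points
#'
#' Drapes the composite texture over the depth map: each pixel becomes a
#' point with `x_mm = column * pixel_scale`, `y_mm = row * pixel_scale`,
#' `z_mm = depth`, carrying its composite intensity.
#'
#' @param recon A `leafpol_recon` from [stack_focus()].
#' @param pixel_scale mm/pixel; defaults to the scale stored on `recon`.
#' @param raw_depth Use the unsmoothed depth map (default `FALSE`).
#'
#' @return A data frame with columns `x_mm`, `y_mm`, `z_mm`, `texture`.
#' @export
reconstruct_3d <- function(recon, pixel_scale = recon$pixel_scale,
                           raw_depth = FALSE) {
  if (is.null(pixel_scale))
    stop_leafpol("pixel scale is required to calibrate x/y coordinates",
                 "leafpol_calibration_error")
  check_scalar(pixel_scale, "pixel_scale", positive = TRUE)
  z <- if (raw_depth) recon$depth_raw_mm else recon$depth_mm
  nr <- nrow(z); nc <- ncol(z)
  data.frame(
    x_mm = rep(seq_len(nc), each = nr) * pixel_scale,
    y_mm = rep(seq_len(nr), times = nc) * pixel_scale,
    z_mm = as.vector(z),
    texture = as.vector(recon$composite)
  )
}
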
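# Small image-filtering primitives used by both the synthetic stack
# generator (defocus blur) and the reconstruction post-filters.
#
# All filters use nearest-edge (replicate) padding, implemented by clamped
# index shifts, so output size always equals input size.

# out[r, c] = m[clamp(r + dr), clamp(c + dc)]
shift_clamp <- function(m, dr, dc) {
  m[clamp_index(seq_len(nrow(m)) + dr, nrow(m)),
    clamp_index(seq_len(ncol(m)) + dc, ncol(m)), drop = FALSE]
}

gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with a symmetric 1-D kernel (rows then columns).
convolve_sep <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  tmp <- 0
  for (i in seq_along(k)) tmp <- tmp + k[i] * shift_clamp(img, i - 1L - r, 0L)
  out <- 0
  for (i in seq_along(k)) out <- out + k[i] * shift_clamp(tmp, 0L, i - 1L - r)
  out
}

# Gaussian blur parameterized by sigma (defocus model for the stack
# generator); sigma 0 is the identity.
blur_gaussian <- function(img, sigma) {
  if (sigma <= 1e-12) return(img)
  convolve_sep(img, gaussian_kernel1d(sigma))
}

# size x size Gaussian smoothing filter with the kernel-width convention
# sigma = size/6 (kernel spans about +/- 3 sigma).
gaussian_filter <- function(img, size = 15L, sigma = size / 6) {
  if (size < 1L) stop_param("filter `size` must be >= 1")
  radius <- (as.integer(size) - 1L) %/% 2L
  convolve_sep(img, gaussian_kernel1d(sigma, radius = radius))
}

# Even-sized median filter.  A size x size window has no center pixel; the
# origin sits at (size/2, size/2) of the window, i.e. offsets run from
# -(size/2 - 1) to +size/2 (window extends one pixel further down/right).
median_filter <- function(img, size = 10L) {
  size <- as.integer(size)
  if (size < 2L) stop_param("median filter `size` must be >= 2")
  half <- size %/% 2L
  offs <- if (size %% 2L == 0L) seq.int(-(half - 1L), half)
          else seq.int(-half, half)
  nr <- nrow(img); nc <- ncol(img)
  vals <- matrix(0, nr * nc, length(offs)^2)
  j <- 0L
  for (dc in offs) for (dr in offs) {
    j <- j + 1L
    vals[, j] <- shift_clamp(img, dr, dc)
  }
  matrix(apply(vals, 1L, stats::median), nr, nc)
}
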
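# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures on disk.

# Regular n-gon of radius r centered at (cx, cy)
regular_polygon <- function(n, r = 1, cx = 0, cy = 0) {
  a <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(a), cy + r * sin(a))
}

# 4-pointed star: 8 alternating vertices at outer/inner radius
star_polygon <- function(outer = 1, inner = 0.5) {
  a <- 2 * pi * (0:7) / 8
  r <- rep(c(outer, inner), 4)
  cbind(r * cos(a), r * sin(a))
}

# Tilted plane (z rising along rows) plus textured cell domes: the standard
# depth-recovery fixture.  Returns the stack with retained ground truth.
make_recovery_stack <- function(seed = 1, n = 96, n_images = 30,
                                step = 0.001) {
  surf <- generate_surface(surface_spec(field_size = n, pixel_scale = 1e-3,
                                        cell_pitch_um = 24,
                                        cell_amplitude_um = 4,
                                        margin_waviness = 0.4), seed = seed)
  plane <- outer(seq(0, 0.018, length.out = n), rep(1, n))
  st <- generate_focus_stack(surf$height_mm + plane, surf$texture,
                             stage_start_mm = 0, stage_step_mm = step,
                             n_images = n_images, blur_coefficient = 800)
  st$texture <- surf$texture  # in-focus texture, for texture-rich masks
  st
}

# Brute-force gradient-magnitude oracle: per-pixel finite differences in a
# plain double loop (central in the interior, one-sided at borders).
sharpness_oracle <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    gy <- if (r == 1) img[2, c] - img[1, c]
          else if (r == nr) img[nr, c] - img[nr - 1, c]
          else (img[r + 1, c] - img[r - 1, c]) / 2
    gx <- if (c == 1) img[r, 2] - img[r, 1]
          else if (c == nc) img[r, nc] - img[r, nc - 1]
          else (img[r, c + 1] - img[r, c - 1]) / 2
    out[r, c] <- sqrt(gx^2 + gy^2)
  }
  out
}

# Independent polygon-area oracle: triangle-fan decomposition from the
# vertex centroid (star-shaped polygons only, which covers the fixtures).
shoelace_oracle <- function(v) {
  c0 <- colMeans(v)
  n <- nrow(v)
  a <- 0
  for (i in seq_len(n)) {
    p <- v[i, ] - c0
    q <- v[i %% n + 1, ] - c0
    a <- a + (p[1] * q[2] - p[2] * q[1]) / 2
  }
  abs(a)
}

# All turns of a closed polygon have the same orientation sign -> convex
is_convex_polygon <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    p <- v[i, ]; q <- v[i %% n + 1, ]; r <- v[(i + 1) %% n + 1, ]
    cr <- (q[1] - p[1]) * (r[2] - q[2]) - (q[2] - p[2]) * (r[1] - q[1])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr)
    else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}
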
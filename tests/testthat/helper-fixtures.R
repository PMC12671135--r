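# Fixture builders and independent oracles used across the test files.

# rasterize a disc into a label matrix (pixel centers at (i-0.5, j-0.5))
draw_disc <- function(dim, center_rc, radius_px, label = 1L, into = NULL) {
  m <- if (is.null(into)) matrix(0L, dim[1L], dim[2L]) else into
  r <- matrix(seq_len(dim[1L]) - 0.5, dim[1L], dim[2L])
  cc <- matrix(seq_len(dim[2L]) - 0.5, dim[1L], dim[2L], byrow = TRUE)
  m[(r - center_rc[1L])^2 + (cc - center_rc[2L])^2 <= radius_px^2] <- label
  m
}

# axis-rotatable capsule: segment from p1 to p2 (pixel coords), half-width w
draw_capsule <- function(dim, p1, p2, halfwidth_px, label = 1L, into = NULL) {
  m <- if (is.null(into)) matrix(0L, dim[1L], dim[2L]) else into
  r <- matrix(seq_len(dim[1L]) - 0.5, dim[1L], dim[2L])
  cc <- matrix(seq_len(dim[2L]) - 0.5, dim[1L], dim[2L], byrow = TRUE)
  v <- p2 - p1
  L2 <- sum(v^2)
  t <- if (L2 == 0) 0 else pmin(pmax(((r - p1[1L]) * v[1L] + (cc - p1[2L]) * v[2L]) / L2, 0), 1)
  d2 <- (r - (p1[1L] + t * v[1L]))^2 + (cc - (p1[2L] + t * v[2L]))^2
  m[d2 <= halfwidth_px^2] <- label
  m
}

# independent brute-force oracle: explicit covariance of pixel coordinates
# (unit-square pixels) and eigen-decomposition
oracle_moments <- function(mask, label, pixel_size_um) {
  idx <- which(mask == label)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  S <- cov(cbind(r, cc)) * (length(idx) - 1) / length(idx) + diag(2) / 12
  if (length(idx) == 1L) S <- diag(2) / 12
  ev <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
  list(area_um2 = length(idx) * pixel_size_um^2,
       aspect_ratio = sqrt(ev[1L] / ev[2L]),
       major_axis_um = 4 * sqrt(ev[1L]) * pixel_size_um,
       minor_axis_um = 4 * sqrt(ev[2L]) * pixel_size_um)
}

# random connected blob: union of discs along a random walk
random_blob <- function(dim = c(64L, 64L), n_steps = 6L, r_range = c(2, 6)) {
  m <- matrix(0L, dim[1L], dim[2L])
  p <- runif(2, dim / 3, 2 * dim / 3)
  for (s in seq_len(n_steps)) {
    m <- draw_disc(dim, p, runif(1, r_range[1L], r_range[2L]), 1L, into = m)
    p <- pmin(pmax(p + runif(2, -4, 4), 8), dim - 8)
  }
  m
}

# a small time-lapse of a drifting disc
drifting_disc_tl <- function(n = 20L, dim = c(64L, 64L), r = 8,
                             drift = c(0.5, 0.3), px = 0.1, dt = 10) {
  frames <- lapply(seq_len(n) - 1L, function(k)
    draw_disc(dim, c(24, 24) + k * drift, r))
  time_lapse(frames, dt, px)
}

# tiny synthetic config for fast tests (dots override the tiny defaults)
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_spores = 6L, grid = c(448L, 448L),
               n_frames = 100L, debris_n = 2L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

expect_rel_equal <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(y), 1e-12)),
              label = paste0("relative difference within ", tol))
}
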
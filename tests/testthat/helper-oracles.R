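# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# brute-force double-loop GLCM: counts pairs at one offset, both voxels in ROI
oracle_glcm <- function(levels, roi, offset, n_levels, symmetric = TRUE) {
  M <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(levels))) {
    for (c in seq_len(ncol(levels))) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 < 1 || r2 > nrow(levels) || c2 < 1 || c2 > ncol(levels)) next
      if (!roi[r, c] || !roi[r2, c2]) next
      i <- levels[r, c] + 1L; j <- levels[r2, c2] + 1L
      M[i, j] <- M[i, j] + 1
      if (symmetric) M[j, i] <- M[j, i] + 1
    }
  }
  if (sum(M) == 0) stop("no pairs")
  M / sum(M)
}

# exact two-sided Wilcoxon signed-rank p by enumeration of all sign patterns
oracle_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# dense numeric profile of a rectangular defect convolved with a Gaussian,
# built by brute-force discrete convolution (not the analytic error function)
oracle_blurred_rect_profile <- function(width, sigma, background = 0,
                                        half_extent = 10, step = 0.01) {
  x <- seq(-half_extent, half_extent, by = step)
  rect <- ifelse(abs(x) <= width / 2, 1, background)
  kx <- seq(0, 4 * sigma, by = step)
  k <- dnorm(c(-rev(kx[-1]), kx), sd = sigma)
  k <- k / sum(k)
  pad <- (length(k) - 1) / 2
  padded <- c(rep(rect[1], pad), rect, rep(rect[length(rect)], pad))
  y <- stats::filter(padded, k, sides = 2)[(pad + 1):(pad + length(x))]
  line_profile(x - x[1], as.numeric(y))
}

# small phantom used by several tests (fits one defect, fast to build)
tiny_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(144, 144), condyle_radius = 12,
               defect_diameters = 5, marrow_texture_sd = 0, ...)
}
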
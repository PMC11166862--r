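# Independent oracles used across the suite.

# Brute-force moving-average SD: enumerate every fully-contained r x r
# window with two explicit loops.
naive_moving_average_sd <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  means <- c()
  for (i in seq_len(n - r + 1)) {
    for (j in seq_len(m - r + 1)) {
      means <- c(means, mean(x[i:(i + r - 1), j:(j + r - 1)]))
    }
  }
  sd(means)
}

# Closed-form radial profile of a disk of radius R convolved with an
# isotropic Gaussian of scale s: the probability that a bivariate normal
# displacement lands inside the disk, i.e. a noncentral chi-square tail.
blurred_disk_coverage <- function(d, R, s) {
  stats::pchisq((R / s)^2, df = 2, ncp = (d / s)^2)
}

# Rotate an image about a center by `angle` (radians) with bilinear
# resampling; used only for rotation-invariance checks on smooth images.
rotate_image <- function(px, center, angle) {
  n <- nrow(px); m <- ncol(px)
  grid_r <- matrix(seq_len(n), n, m)
  grid_c <- matrix(seq_len(m), n, m, byrow = TRUE)
  dr <- grid_r - center[1]; dc <- grid_c - center[2]
  src_r <- center[1] + cos(angle) * dr - sin(angle) * dc
  src_c <- center[2] + sin(angle) * dr + cos(angle) * dc
  inside <- src_r >= 1 & src_r <= n & src_c >= 1 & src_c <= m
  out <- matrix(mean(px), n, m)
  out[inside] <- effcnr:::bilinear_sample(px, src_r[inside], src_c[inside])
  out
}

# Ground-truth sde_params with the half-maximum placed at t_half.
params_with_half_at <- function(c0, sigma, t_half, baseline = 0, t_total = 50) {
  a <- -log(1e-13) / (t_total - t_half)
  sde_params(c0 = c0, sigma = sigma, gamma = a - sigma^2 / 2,
             baseline = baseline, t_total = t_total)
}
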
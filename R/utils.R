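# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Circular (wrap-around) distances 0, 1, ..., n/2, ..., -1 for an FFT grid.
circ_dist <- function(n) {
  half <- floor(n / 2)
  d <- c(0:half, if (n - half - 1 > 0) -((n - half - 1):1) else integer(0))
  d[seq_len(n)]
}

gauss_kernel_1d <- function(n, sigma) {
  k <- exp(-circ_dist(n)^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smoothing of a matrix by FFT convolution with periodic boundary.
# Periodic wrap keeps the field stationary; callers must keep structures of
# interest at least ~3*sigma away from the borders.
smooth_gaussian <- function(x, sigma) {
  stopifnot(is.matrix(x), sigma > 0)
  kern <- outer(gauss_kernel_1d(nrow(x), sigma), gauss_kernel_1d(ncol(x), sigma))
  Re(stats::fft(stats::fft(x) * stats::fft(kern), inverse = TRUE)) / length(x)
}

# Bilinear interpolation of matrix `px` at fractional (row, col) positions.
# Positions are 1-based with pixel centers at integer coordinates and must
# lie inside [1, nrow] x [1, ncol].
bilinear_sample <- function(px, row, col) {
  i0 <- pmin(pmax(floor(row), 1), nrow(px) - 1L)
  j0 <- pmin(pmax(floor(col), 1), ncol(px) - 1L)
  fr <- row - i0
  fc <- col - j0
  (1 - fr) * (1 - fc) * px[cbind(i0, j0)] +
    (1 - fr) * fc * px[cbind(i0, j0 + 1L)] +
    fr * (1 - fc) * px[cbind(i0 + 1L, j0)] +
    fr * fc * px[cbind(i0 + 1L, j0 + 1L)]
}

nearest_sample <- function(px, row, col) {
  i <- pmin(pmax(round(row), 1), nrow(px))
  j <- pmin(pmax(round(col), 1), ncol(px))
  px[cbind(i, j)]
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
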
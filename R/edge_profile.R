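new_edge_profile <- function(radii, mean_hu, n_samples, source = "measured") {
  structure(
    list(radii = as.numeric(radii), mean_hu = as.numeric(mean_hu),
         n_samples = as.integer(n_samples), source = source),
    class = "edge_profile"
  )
}

#' Estimate the center of a circular signal
#'
#' Intensity-weighted centroid of the pixels exceeding `hu_threshold`
#' (weights are the HU excess over the threshold), giving a sub-pixel
#' `(row, col)` estimate. Intended for clean or lightly noisy images; for
#' noisy images pass a threshold well above the noise floor, or supply the
#' known center directly to [radial_profile()].
#'
#' @param image a [ct_image] or matrix.
#' @param hu_threshold pixels strictly above this CT number are used.
#' @return numeric `(row, col)` center, 1-based.
#' @export
estimate_center <- function(image, hu_threshold) {
  px <- as_pixels(image)
  mask <- px > hu_threshold
  if (!any(mask)) stop("no pixels above ", hu_threshold, " HU: empty mask")
  idx <- which(mask, arr.ind = TRUE)
  w <- px[mask] - hu_threshold
  if (sum(w) <= 0) stop("degenerate weights above threshold")
  c(row = sum(idx[, 1] * w) / sum(w), col = sum(idx[, 2] * w) / sum(w))
}

#' Angle-averaged radial edge profile
#'
#' Places `n_angles` radial line segments of `ray_length` pixels around
#' `center` (uniform angular spacing) and, for each integer radius
#' `d = 1..ray_length`, averages the interpolated CT numbers of all rays at
#' distance `d` from the center. The profile therefore consists of
#' `ray_length` mean CT numbers, oriented signal-to-background: the first
#' point is nearest the center.
#'
#' @param image a [ct_image] or matrix (HU).
#' @param center sub-pixel `(row, col)` signal center; defaults to
#'   [estimate_center()] at half the image's HU range.
#' @param n_angles number of rays (default 360, i.e. 1 degree apart).
#' @param ray_length profile length in pixels (default 50).
#' @param interpolation `"bilinear"` (default; rotation-stable) or
#'   `"nearest"` for strict pixel-value sampling.
#' @return An object of class `edge_profile` with fields `radii` (1..T),
#'   `mean_hu` and `n_samples` (rays contributing per radius; all rays must
#'   fit inside the image, so this equals `n_angles`).
#' @examples
#' img <- disk_phantom(phantom_spec(shape = c(128, 128)))
#' prof <- radial_profile(img)
#' plot(prof)
#' @export
radial_profile <- function(image, center = NULL, n_angles = 360L,
                           ray_length = 50L,
                           interpolation = c("bilinear", "nearest")) {
  px <- as_pixels(image)
  interpolation <- match.arg(interpolation)
  n_angles <- as.integer(n_angles)
  ray_length <- as.integer(ray_length)
  if (n_angles < 1L) stop("n_angles must be >= 1")
  if (ray_length < 2L) stop("ray_length must be >= 2")
  if (is.null(center)) center <- estimate_center(px, mean(range(px)))
  center <- rep_len(as.numeric(center), 2L)

  max_usable <- floor(min(center[1] - 1, nrow(px) - center[1],
                          center[2] - 1, ncol(px) - center[2]))
  if (ray_length > max_usable) {
    stop(sprintf("rays of length %d exit the image; maximum usable radius from (%g, %g) is %d",
                 ray_length, center[1], center[2], max_usable))
  }
  ang <- (seq_len(n_angles) - 1L) * 2 * pi / n_angles
  d <- seq_len(ray_length)
  rows <- center[1] + outer(d, sin(ang))
  cols <- center[2] + outer(d, cos(ang))
  vals <- if (interpolation == "bilinear") {
    bilinear_sample(px, as.vector(rows), as.vector(cols))
  } else {
    nearest_sample(px, as.vector(rows), as.vector(cols))
  }
  vals <- matrix(vals, ray_length, n_angles)
  new_edge_profile(radii = d, mean_hu = rowMeans(vals),
                   n_samples = rep(n_angles, ray_length))
}

#' @export
print.edge_profile <- function(x, ...) {
  cat(sprintf("Edge profile: %d radii (%g..%g px), HU range [%.1f, %.1f]\n",
              length(x$radii), min(x$radii), max(x$radii),
              min(x$mean_hu), max(x$mean_hu)))
  invisible(x)
}

#' @export
as.data.frame.edge_profile <- function(x, ...) {
  data.frame(radius = x$radii, mean_hu = x$mean_hu, n_samples = x$n_samples)
}

#' @param x an `edge_profile`.
#' @param ... passed to [graphics::plot()].
#' @rdname radial_profile
#' @export
plot.edge_profile <- function(x, ...) {
  graphics::plot(x$radii, x$mean_hu, xlab = "radius (px)",
                 ylab = "mean CT number (HU)", pch = 16, ...)
  invisible(x)
}

#' Measured differential profile
#'
#' Subtracts adjacent mean CT numbers of an edge profile,
#' `delta[i] = mean_hu[i] - mean_hu[i+1]`, the discrete slit-like profile of
#' the edge. A bright insert yields a positive peak at the edge.
#'
#' @param profile an `edge_profile` (length >= 2).
#' @return data frame with columns `radius` (left point of each pair) and
#'   `delta_hu`, of length one less than the profile.
#' @export
differential_profile <- function(profile) {
  stopifnot(inherits(profile, "edge_profile"))
  n <- length(profile$mean_hu)
  if (n < 2L) stop("profile must contain at least 2 points")
  data.frame(radius = profile$radii[-n],
             delta_hu = -diff(profile$mean_hu))
}
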
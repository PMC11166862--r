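#' CT image container
#'
#' A minimal container for a single 2-D CT slice: a numeric matrix of CT
#' numbers in Hounsfield units (HU) plus the pixel spacing in mm. All
#' coordinates in this package are 1-based `(row, col)` pairs with pixel
#' centers at integer coordinates, matching R matrix indexing.
#'
#' @param pixels numeric matrix of CT numbers (HU). All values must be finite.
#' @param spacing pixel spacing in mm per pixel as `(row, col)`; a single
#'   value is recycled. Must be positive.
#' @param source free-form provenance string (file name, phantom spec, ...).
#' @return An object of class `ct_image`: a list with elements `pixels`,
#'   `spacing` and `source`.
#' @examples
#' img <- ct_image(matrix(rnorm(64, sd = 10), 8, 8))
#' dim(img)
#' @export
ct_image <- function(pixels, spacing = c(1, 1), source = "in-memory") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (length(pixels) == 0L) stop("image must contain at least one pixel")
  if (!all(is.finite(pixels))) stop("all CT numbers must be finite")
  spacing <- rep_len(as.numeric(spacing), 2L)
  if (!all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("pixel spacing must be positive and finite")
  }
  structure(
    list(pixels = unname(pixels), spacing = spacing,
         source = as.character(source)[1L]),
    class = "ct_image"
  )
}

#' @export
as.matrix.ct_image <- function(x, ...) x$pixels

#' @export
dim.ct_image <- function(x) dim(x$pixels)

#' @export
print.ct_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("CT image: %d x %d pixels, spacing %.4g x %.4g mm\n",
              d[1], d[2], x$spacing[1], x$spacing[2]))
  cat(sprintf("  HU range [%.1f, %.1f], mean %.1f, sd %.2f\n",
              min(x$pixels), max(x$pixels), mean(x$pixels),
              stats::sd(as.vector(x$pixels))))
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' @param wl,ww display window level and width in HU (defaults show the
#'   full HU range of the image).
#' @rdname ct_image
#' @export
plot.ct_image <- function(x, wl = NULL, ww = NULL, ...) {
  px <- x$pixels
  if (is.null(wl)) wl <- mean(range(px))
  if (is.null(ww)) ww <- max(diff(range(px)), 1)
  lo <- wl - ww / 2
  z <- pmin(pmax((px - lo) / ww, 0), 1)
  # transpose/flip so that row 1 is displayed at the top
  graphics::image(t(z)[, nrow(z):1, drop = FALSE], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(z) / ncol(z), ...)
  invisible(x)
}

# Coerce matrices / ct_images uniformly inside the package.
as_pixels <- function(x) {
  if (inherits(x, "ct_image")) x$pixels else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}
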
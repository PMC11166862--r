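#' Read a CT image from disk
#'
#' Supported formats: plain CSV grids (values read verbatim as HU), 16-bit
#' TIFF and 16-bit PNG rasters. Raster formats cannot store negative HU, so
#' they are accompanied by a JSON "sidecar" file (`<path>.json`) written by
#' [write_ct_image()] that records the affine map back to HU
#' (`HU = offset + scale * stored`) and the pixel spacing. Rasters without a
#' sidecar are read with `offset = 0`, `scale = 1`.
#'
#' @param path file to read.
#' @param format one of `"auto"` (by extension), `"csv"`, `"tiff"`, `"png16"`.
#' @return A [ct_image].
#' @seealso [write_ct_image()]
#' @export
read_ct_image <- function(path, format = c("auto", "csv", "tiff", "png16")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tif = , tiff = "tiff", png = "png16",
      stop("cannot infer image format from extension of ", path)
    )
  }
  if (format == "csv") {
    nf <- utils::count.fields(path, sep = ",")
    if (length(unique(nf)) != 1L) {
      stop("non-rectangular CSV grid: rows have ", paste(unique(nf), collapse = "/"),
           " fields")
    }
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    if (!is.numeric(m)) stop("CSV grid contains non-numeric entries")
    return(ct_image(m, source = basename(path)))
  }
  sidecar <- sidecar_path(path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else
    list(offset = 0, scale = 1, pixel_spacing = c(1, 1))
  stored <- if (format == "tiff") {
    s <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(s)) != 2L) stop("only single-channel grayscale TIFF is supported")
    s
  } else {
    s <- png::readPNG(path)
    if (length(dim(s)) != 2L) stop("only single-channel grayscale PNG is supported")
    round(s * 65535)  # readPNG rescales 16-bit samples to [0, 1]
  }
  hu <- meta$offset + meta$scale * stored
  ct_image(hu, spacing = meta$pixel_spacing, source = basename(path))
}

#' Write a CT image to disk
#'
#' CSV writes the HU values verbatim. TIFF quantizes to 16 bits over the
#' image's HU range and writes a JSON sidecar (`<path>.json`) with the
#' `offset`/`scale` needed to map stored integers back to HU, plus the pixel
#' spacing. 16-bit PNG output is not supported by the PNG writer available
#' here; PNG is read-only.
#'
#' @param x a [ct_image] (or a plain matrix of HU values).
#' @param path destination file.
#' @param format `"auto"` (by extension), `"csv"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_ct_image <- function(x, path, format = c("auto", "csv", "tiff")) {
  format <- match.arg(format)
  img <- if (inherits(x, "ct_image")) x else ct_image(x)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tif = , tiff = "tiff",
      stop("cannot infer image format from extension of ", path)
    )
  }
  if (format == "csv") {
    utils::write.table(img$pixels, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  rng <- range(img$pixels)
  scale <- if (diff(rng) > 0) diff(rng) / 65535 else 1
  stored <- round((img$pixels - rng[1]) / scale)
  tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(offset = rng[1], scale = scale, pixel_spacing = img$spacing,
         source = img$source),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")
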
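#' ROI mean and SD
#'
#' Sample mean and sample SD (n-1 denominator) of the pixels inside a
#' square ROI.
#'
#' @param image a [ct_image] or matrix (HU).
#' @param roi a [square_roi]; defaults to a 40x40 ROI at the image center.
#' @return Named numeric `c(mean, sd)` in HU.
#' @export
roi_stats <- function(image, roi = NULL) {
  px <- roi_pixels(image, roi)
  c(mean = mean(px), sd = stats::sd(as.vector(px)))
}

#' Conventional contrast-to-noise ratio
#'
#' `CNR = (p_signal - p_background) / noise_sd`: the difference between the
#' mean CT numbers of the signal and background regions, divided by the
#' background noise SD. Signed.
#'
#' @param p_signal mean CT number of the signal region (HU).
#' @param p_background mean CT number of the background region (HU).
#' @param noise_sd SD of the background region (HU, > 0).
#' @return Dimensionless CNR.
#' @examples
#' conventional_cnr(100, 40, 30)  # 2
#' @export
conventional_cnr <- function(p_signal, p_background, noise_sd) {
  stopifnot(is_scalar_num(p_signal), is_scalar_num(p_background),
            is_scalar_num(noise_sd))
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  (p_signal - p_background) / noise_sd
}

#' Effective contrast-to-noise ratio
#'
#' `|effective contrast| / sigma_apparent`: the blur-attenuated contrast
#' divided by the texture-aware apparent-noise index. The absolute value
#' makes the index non-negative, as befits a detectability measure.
#'
#' @param effective_contrast contrast times sharpness index (HU; see
#'   [effective_contrast()]).
#' @param sigma_apparent apparent-noise index (HU, > 0; see
#'   [apparent_noise()]).
#' @return Dimensionless effective CNR.
#' @examples
#' effective_cnr(30, 15)  # 2
#' @export
effective_cnr <- function(effective_contrast, sigma_apparent) {
  stopifnot(is_scalar_num(effective_contrast), is_scalar_num(sigma_apparent))
  if (sigma_apparent <= 0) stop("sigma_apparent must be > 0")
  abs(effective_contrast) / sigma_apparent
}

#' Full effective-CNR analysis of a noise image and a signal image
#'
#' Runs the whole chain: apparent-noise estimation on a homogeneous ROI of
#' the noise image, radial edge-profile extraction and SDE edge-model
#' fitting on the signal image, and assembly of both the conventional and
#' the effective CNR. Noise and signal may come from different images (in
#' practice noise is measured in a uniform phantom region and contrast on a
#' magnified insert image); both provenances are recorded.
#'
#' Conventional CNR uses the mean of a small square ROI at the signal
#' center as `p_signal`, and the noise ROI's mean and SD as `p_background`
#' and `noise_sd`.
#'
#' @param noise_image [ct_image] (or matrix) with a homogeneous region.
#' @param signal_image [ct_image] (or matrix) containing the circular signal.
#' @param signal_center `(row, col)` center of the signal; estimated via
#'   [estimate_center()] when omitted.
#' @param noise_roi [square_roi] for the noise measurement (default 40x40
#'   at the center of `noise_image`).
#' @param signal_roi [square_roi] for `p_signal` (default 10x10 at
#'   `signal_center`).
#' @param n_angles,ray_length,interpolation forwarded to [radial_profile()].
#' @param r_values,fit_range forwarded to [apparent_noise()].
#' @param ... forwarded to [fit_edge_model()].
#' @return An object of class `cnr_report`: list with `p_signal`,
#'   `p_background`, `noise_sd`, `conventional_cnr`, `sigma_apparent`,
#'   `c0`, `sharpness_index`, `effective_contrast`, `effective_cnr`, the
#'   underlying `noise` ([apparent_noise]), `fit` ([fit_edge_model()]
#'   result), `profile`, and `provenance`.
#' @examples
#' spec <- phantom_preset("dlr_like", seed = 3)
#' noise_img <- ct_image(noise_field(c(64, 64), spec$noise_sd_hu,
#'                                   spec$noise_corr_sigma, seed = 3))
#' signal_img <- disk_phantom(spec)
#' rep <- effective_cnr_analysis(noise_img, signal_img,
#'                               signal_center = spec$insert_center)
#' rep
#' @export
effective_cnr_analysis <- function(noise_image, signal_image,
                                   signal_center = NULL,
                                   noise_roi = NULL, signal_roi = NULL,
                                   n_angles = 360L, ray_length = 50L,
                                   interpolation = "bilinear",
                                   r_values = 1:20, fit_range = c(5, 10),
                                   ...) {
  noise_image <- if (inherits(noise_image, "ct_image")) noise_image else ct_image(noise_image)
  signal_image <- if (inherits(signal_image, "ct_image")) signal_image else ct_image(signal_image)

  noise <- withCallingHandlers(
    apparent_noise(noise_image, roi = noise_roi, r_values = r_values,
                   fit_range = fit_range),
    error = function(e) stop("apparent-noise stage: ", conditionMessage(e))
  )
  bg <- roi_stats(noise_image, noise_roi)

  if (is.null(signal_center)) {
    signal_center <- estimate_center(signal_image,
                                     mean(range(as_pixels(signal_image))))
  }
  if (is.null(signal_roi)) signal_roi <- square_roi(signal_center, 10L)
  sig <- roi_stats(signal_image, signal_roi)

  profile <- tryCatch(
    radial_profile(signal_image, center = signal_center, n_angles = n_angles,
                   ray_length = ray_length, interpolation = interpolation),
    error = function(e) stop("edge-profile stage: ", conditionMessage(e))
  )
  fit <- tryCatch(
    fit_edge_model(profile, ...),
    error = function(e) stop("edge-model stage: ", conditionMessage(e))
  )
  si <- sharpness_index(fit)
  eff_c <- fit$params$c0 * si$sharpness_index

  structure(
    list(p_signal = unname(sig["mean"]),
         p_background = unname(bg["mean"]),
         noise_sd = unname(bg["sd"]),
         conventional_cnr = conventional_cnr(unname(sig["mean"]),
                                             unname(bg["mean"]),
                                             unname(bg["sd"])),
         sigma_apparent = noise$sigma_apparent,
         c0 = fit$params$c0,
         sharpness_index = si$sharpness_index,
         effective_contrast = eff_c,
         effective_cnr = effective_cnr(eff_c, noise$sigma_apparent),
         noise = noise,
         fit = fit,
         profile = profile,
         provenance = list(noise_source = noise_image$source,
                           signal_source = signal_image$source,
                           signal_center = signal_center)),
    class = "cnr_report"
  )
}

#' @export
print.cnr_report <- function(x, ...) {
  cat("Effective CNR report\n")
  cat(sprintf("  noise:    SD %.2f HU, sigma_apparent %.2f HU  [%s]\n",
              x$noise_sd, x$sigma_apparent, x$provenance$noise_source))
  cat(sprintf("  signal:   P_signal %.2f HU, P_background %.2f HU  [%s]\n",
              x$p_signal, x$p_background, x$provenance$signal_source))
  cat(sprintf("  contrast: C0 %.2f HU, sharpness index %.3f, effective contrast %.2f HU\n",
              x$c0, x$sharpness_index, x$effective_contrast))
  cat(sprintf("  conventional CNR: %.3f\n", x$conventional_cnr))
  cat(sprintf("  effective CNR:    %.3f\n", x$effective_cnr))
  invisible(x)
}

#' @export
as.data.frame.cnr_report <- function(x, ...) {
  data.frame(p_signal = x$p_signal, p_background = x$p_background,
             noise_sd = x$noise_sd, conventional_cnr = x$conventional_cnr,
             sigma_apparent = x$sigma_apparent, c0 = x$c0,
             sharpness_index = x$sharpness_index,
             effective_contrast = x$effective_contrast,
             effective_cnr = x$effective_cnr)
}

#' @export
summary.cnr_report <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$noise)
  print(object$fit)
  invisible(object)
}
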
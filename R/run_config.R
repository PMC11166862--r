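config_schema <- list(
  seed = "integer",
  noise_roi = c("center", "side"),
  radial = c("n_angles", "ray_length", "interpolation"),
  sde = c("t_total", "lambda", "dt"),
  fit = c("lower", "upper", "contrast_floor"),
  phantom = c("shape", "background_hu", "insert_contrast_hu", "insert_center",
              "insert_radius", "edge_blur_sigma", "noise_sd_hu",
              "noise_corr_sigma", "seed", "preset"),
  output = "character"
)

#' Analysis run configuration
#'
#' A validated bag of options for a full analysis run (or phantom
#' simulation): the noise ROI, the radial-profile settings, the fixed SDE
#' model constants, fit options, an optional phantom specification and the
#' seed. Unknown keys — at the top level or inside the nested sections —
#' are rejected rather than silently ignored.
#'
#' @param seed integer seed controlling all randomness of a run.
#' @param noise_roi list with `center` and/or `side`.
#' @param radial list with any of `n_angles`, `ray_length`, `interpolation`.
#' @param sde list with any of `t_total`, `lambda`, `dt`.
#' @param fit list with any of `lower`, `upper`, `contrast_floor`.
#' @param phantom list of [phantom_spec()] arguments and/or a `preset` name.
#' @param output output path prefix.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, noise_roi = list(), radial = list(),
                       sde = list(), fit = list(), phantom = list(),
                       output = NULL) {
  cfg <- list(seed = as.integer(seed), noise_roi = noise_roi, radial = radial,
              sde = sde, fit = fit, phantom = phantom, output = output)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown)) {
    stop("unknown run-config keys: ", paste(unknown, collapse = ", "))
  }
  for (section in c("noise_roi", "radial", "sde", "fit", "phantom")) {
    keys <- names(cfg[[section]])
    bad <- setdiff(keys, config_schema[[section]])
    if (length(bad)) {
      stop("unknown keys in run-config section '", section, "': ",
           paste(bad, collapse = ", "))
    }
  }
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Read / write run configurations
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), decided by extension. Configs
#' are validated on the way in and out.
#'
#' @param path file path.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- switch(tolower(tools::file_ext(path)),
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", path)
  )
  if (!is.list(cfg)) stop("config must be a mapping/object")
  validate_run_config(cfg)
}

#' @param cfg a `run_config` (or plain list, validated before writing).
#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  cfg <- validate_run_config(unclass(cfg))
  switch(tolower(tools::file_ext(path)),
    yml = , yaml = yaml::write_yaml(unclass(cfg), path),
    json = jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                                digits = NA, null = "null"),
    stop("unsupported config extension: ", path)
  )
  invisible(path)
}
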
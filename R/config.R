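# Analysis configuration: imaging geometry, filtering and clustering
# parameters, with the two parameter presets used for thioflavin-X and
# aptamer-PAINT processing.

.config_defaults <- list(
  fov_size      = 20000,   # nm
  pixel_size_sr = 98.8,    # nm, super-resolution camera pixel
  pixel_size_dl = 237,     # nm, diffraction-limited camera pixel
  n_frames      = 8000L,
  exposure_ms   = 50,
  eps           = 75,      # nm, DBSCAN detection radius
  min_pts       = 9L,      # DBSCAN minimum localization threshold
  min_signal    = 100,     # photons, filter lower bound
  max_precision = 20,      # nm, filter upper bound
  hist_bin_width = 10,     # nm
  render_blur   = 20,      # nm
  seed          = 1L
)

.config_presets <- list(
  # thioflavin-X transient-binding imaging
  thx   = list(min_signal = 100, max_precision = 20, eps = 75,  min_pts = 9L),
  # aptamer DNA-PAINT imaging
  paint = list(min_signal = 60,  max_precision = 40, eps = 200, min_pts = 10L)
)

#' Build an analysis configuration
#'
#' Returns the full set of imaging, filtering and clustering parameters used
#' throughout the pipeline, with documented defaults. Two named presets bundle
#' the filter/cluster settings of the two imaging modes: `"thx"`
#' (thioflavin-X: minimum signal 100 photons, maximum precision 20 nm,
#' eps 75 nm, minPts 9) and `"paint"` (aptamer PAINT: 60 photons, 40 nm,
#' eps 200 nm, minPts 10). Explicit arguments override preset values, which
#' override defaults.
#'
#' @param ... named parameter overrides (see Details for names).
#' @param preset optional preset name, `"thx"` or `"paint"`.
#'
#' @details Parameters (units): `fov_size` (nm), `pixel_size_sr` (nm),
#'   `pixel_size_dl` (nm), `n_frames`, `exposure_ms`, `eps` (nm), `min_pts`,
#'   `min_signal` (photons), `max_precision` (nm), `hist_bin_width` (nm),
#'   `render_blur` (nm), `seed`.
#'
#' @return A named list of class `"analysis_config"`.
#' @examples
#' analysis_config(preset = "paint")$eps  # 200
#' @export
analysis_config <- function(..., preset = NULL) {
  cfg <- .config_defaults
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(.config_presets))
    cfg[names(.config_presets[[preset]])] <- .config_presets[[preset]]
  }
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("all configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  cfg <- validate_config(cfg)
  class(cfg) <- c("analysis_config", "list")
  cfg
}

#' Validate an analysis configuration
#'
#' Checks the invariants of each configuration key and fails with a message
#' naming the offending key.
#'
#' @param cfg a named list of configuration values.
#' @return The validated configuration (with integer keys coerced).
#' @export
validate_config <- function(cfg) {
  num_pos <- c("fov_size", "pixel_size_sr", "pixel_size_dl", "exposure_ms",
               "eps", "max_precision", "hist_bin_width", "render_blur")
  for (key in num_pos) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("invalid value for '%s': must be a positive number", key),
           call. = FALSE)
  }
  for (key in c("n_frames", "min_pts")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != round(v))
      stop(sprintf("invalid value for '%s': must be a positive integer", key),
           call. = FALSE)
    cfg[[key]] <- as.integer(v)
  }
  if (!is.numeric(cfg$min_signal) || length(cfg$min_signal) != 1L ||
      !is.finite(cfg$min_signal) || cfg$min_signal < 0)
    stop("invalid value for 'min_signal': must be a non-negative number",
         call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed))
    stop("invalid value for 'seed': must be a finite number", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Load an analysis configuration from a YAML/JSON file
#'
#' Absent keys are filled with the documented defaults; a `preset` key selects
#' a parameter preset (`"thx"` or `"paint"`) before the file's explicit keys
#' are applied.
#'
#' @param path path to a YAML (or JSON, a YAML subset) configuration file.
#' @return An [analysis_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse config file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a mapping", call. = FALSE)
  preset <- raw$preset
  raw$preset <- NULL
  do.call(analysis_config, c(raw, list(preset = preset)))
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  for (key in names(x))
    cat(sprintf("  %-14s %s\n", key, format(x[[key]])))
  invisible(x)
}
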
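#' Pipeline configuration
#'
#' Bundles every tunable parameter of the measurement pipeline. Only the
#' distance filter bounds come from the underlying measurement protocol
#' (400-1200 nm for ~4x expanded samples; callers analyzing unexpanded
#' images must override them); the remaining values are conservative
#' processing choices, all exposed here and echoed into `summary.json`.
#'
#' @param mode `"one_channel"` (axis channel only; the midline is estimated
#'   from the axis signal itself) or `"two_channel"` (a central-element
#'   channel guides the spline).
#' @param blur_sigma_px Gaussian blur applied before thresholding and before
#'   profile sampling, in pixels.
#' @param min_distance_nm,max_distance_nm peak-to-peak distances outside this
#'   closed interval are discarded.
#' @param profile_halflength_nm profiles extend this far to both sides of the
#'   spline. Must be at least `max_distance_nm` so a maximally separated
#'   bimodal pair fits inside one profile.
#' @param profile_step_nm sampling step along a profile; default
#'   (`NULL`) resolves to half the pixel size at run time.
#' @param histogram_bin_nm bin width of the distance histogram.
#' @param min_line_length_px traced centerlines shorter than this are dropped.
#' @param spline_smoothing smoothing parameter (`spar` of
#'   [stats::smooth.spline()]); 0 interpolates exactly.
#' @param breakpoint_angle_deg direction change between successive 5-pixel
#'   chords above which a traced line is split.
#' @param enclosed_only if `TRUE` (the standard behavior for helical
#'   structures) profile sources are restricted to flood-fill-enclosed
#'   in-plane regions; set `FALSE` for structures that enclose nothing,
#'   e.g. straight parallel ridges.
#' @param profile_interp interpolation used when sampling profiles:
#'   `"cubic"` (Catmull-Rom; sub-pixel peak positions are unbiased) or
#'   `"bilinear"` (piecewise linear; maxima lock onto pixel knots).
#' @param fit_window_nm numeric length-2 window (lo, hi) restricting the
#'   half-norm fit, or `NULL` for the full histogram range.
#' @param seed integer seed forwarded to any stochastic component.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("one_channel", "two_channel"),
                            blur_sigma_px = 1.0,
                            min_distance_nm = 400,
                            max_distance_nm = 1200,
                            profile_halflength_nm = 1300,
                            profile_step_nm = NULL,
                            histogram_bin_nm = 10,
                            min_line_length_px = 10L,
                            spline_smoothing = 0.7,
                            breakpoint_angle_deg = 60,
                            enclosed_only = TRUE,
                            profile_interp = c("cubic", "bilinear"),
                            fit_window_nm = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  profile_interp <- match.arg(profile_interp)
  cfg <- list(mode = mode,
              blur_sigma_px = blur_sigma_px,
              min_distance_nm = min_distance_nm,
              max_distance_nm = max_distance_nm,
              profile_halflength_nm = profile_halflength_nm,
              profile_step_nm = profile_step_nm,
              histogram_bin_nm = histogram_bin_nm,
              min_line_length_px = as.integer(min_line_length_px),
              spline_smoothing = spline_smoothing,
              breakpoint_angle_deg = breakpoint_angle_deg,
              enclosed_only = isTRUE(enclosed_only),
              profile_interp = profile_interp,
              fit_window_nm = fit_window_nm,
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$blur_sigma_px > 0,
            cfg$min_distance_nm >= 0,
            cfg$max_distance_nm > cfg$min_distance_nm,
            cfg$profile_halflength_nm > 0,
            cfg$histogram_bin_nm > 0,
            cfg$min_line_length_px >= 2L,
            cfg$spline_smoothing >= 0,
            cfg$breakpoint_angle_deg > 0, cfg$breakpoint_angle_deg < 180)
  if (cfg$profile_halflength_nm < cfg$max_distance_nm)
    stop("profile_halflength_nm must be >= max_distance_nm")
  if (!is.null(cfg$profile_step_nm) && cfg$profile_step_nm <= 0)
    stop("profile_step_nm must be positive")
  if (!is.null(cfg$fit_window_nm) &&
      (length(cfg$fit_window_nm) != 2L ||
       cfg$fit_window_nm[2L] <= cfg$fit_window_nm[1L]))
    stop("fit_window_nm must be c(lo, hi) with hi > lo")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML key-value file
#'
#' Keys mirror the [pipeline_config()] argument names exactly; unknown keys
#' are an error so typos cannot silently fall back to defaults. Values given
#' in `overrides` (e.g. from command-line flags) win over the file.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list of values overriding the file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

# step resolved against the image actually being profiled
resolved_step_nm <- function(cfg, pixel_size_nm) {
  if (is.null(cfg$profile_step_nm)) pixel_size_nm / 2 else cfg$profile_step_nm
}
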
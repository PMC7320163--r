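# condition helpers: usage errors (bad input, exit 1) vs analysis failures
# (degenerate images, exit 2)
stop_usage <- function(msg) {
  stop(structure(class = c("lp_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
stop_analysis <- function(msg) {
  stop(structure(class = c("lp_analysis_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

lp_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}

#' Run the full strand-distance measurement pipeline
#'
#' Executes the complete chain on in-memory channels: guide-channel
#' segmentation (blur, Otsu, skeletonize, trace, spline; from the central
#' channel in two-channel mode or from the merged axis channel in
#' one-channel mode), flood-fill selection of enclosed in-plane regions on
#' the axis channel, perpendicular profile extraction, per-profile
#' peak-to-peak distances, bounds filtering, histogramming, the half-normal
#' cutoff fit, and peak-centered profile averaging.
#'
#' @param axis axis-protein [channel_image()] (the channel that is profiled).
#' @param central optional central-element [channel_image()] guiding the
#'   spline (required in `two_channel` mode).
#' @param config a [pipeline_config()].
#' @param verbose log per-stage counts via [message()].
#' @return list of class `pipeline_result` with elements `distances`
#'   (data.frame), `histogram`, `fit`, `per_line_average_profiles`,
#'   `image_average_profile`, `counts` and `config`.
#' @export
run_pipeline <- function(axis, central = NULL,
                         config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(axis, "channel_image"))
  assert_pipeline_image(axis)
  if (config$mode == "two_channel" && is.null(central))
    stop_usage("two_channel mode requires a central channel")

  splines <- if (config$mode == "two_channel") {
    stopifnot(inherits(central, "channel_image"))
    if (!identical(dim(central$pixels), dim(axis$pixels)))
      stop_usage("axis and central channels differ in shape")
    segment_to_splines(central, config$blur_sigma_px, config)
  } else {
    estimate_axis_one_channel(axis, config)
  }
  lp_log(verbose, "traced %d centerline(s)", length(splines))

  axis_blur <- gaussian_blur(axis, config$blur_sigma_px)
  enclosed <- NULL
  if (config$enclosed_only) {
    axis_mask <- otsu_binarize(axis_blur)
    enclosed <- find_enclosed_regions(axis_mask)
    lp_log(verbose, "enclosed region: %d px", sum(enclosed))
  }
  sources <- select_sources(splines, enclosed, axis$pixel_size_nm)
  if (is.null(sources) || nrow(sources) == 0L)
    stop_analysis("no profile sources inside enclosed regions")
  lp_log(verbose, "selected %d source(s)", nrow(sources))

  profiles <- lapply(seq_len(nrow(sources)), function(i)
    extract_profile(axis_blur, sources[i, ], config))
  ok <- vapply(profiles, function(p) isTRUE(p$ok), logical(1L))
  lp_log(verbose, "extracted %d profile(s), %d out of bounds",
         sum(ok), sum(!ok))

  dists <- lapply(profiles, peak_to_peak_distance)
  dists <- filter_distances(dists, config)
  dist_nm <- vapply(dists, function(d)
    if (is.na(d$distance_nm)) NA_real_ else d$distance_nm, numeric(1L))
  kept <- vapply(dists, function(d) isTRUE(d$kept), logical(1L))
  reasons <- vapply(dists, function(d) d$reason, character(1L))
  distances_df <- data.frame(
    profile_id = seq_len(nrow(sources)),
    line_id = sources$line_id,
    source_row = round(sources$y_nm / axis$pixel_size_nm) + 1L,
    source_col = round(sources$x_nm / axis$pixel_size_nm) + 1L,
    distance_nm = dist_nm, kept = kept, reason = reasons)
  n_valid <- sum(!is.na(dist_nm))
  lp_log(verbose, "%d bimodal distance(s): %d kept, %d discarded",
         n_valid, sum(kept), n_valid - sum(kept))
  if (!any(kept))
    stop_analysis("no distances inside the filter bounds")

  hist <- histogram_distances(dist_nm[kept], config$histogram_bin_nm,
                              c(config$min_distance_nm, config$max_distance_nm))
  fit <- tryCatch(fit_half_norm(hist, config$fit_window_nm),
                  error = function(e) {
                    warning("half-norm fit failed: ", conditionMessage(e))
                    NULL
                  })
  if (!is.null(fit))
    lp_log(verbose, "half-norm fit: c = %.1f nm (stderr %.2f)",
           fit$c, fit$c_stderr)

  avgs <- align_and_average(profiles, dists)
  counts <- list(lines_traced = length(splines),
                 sources_selected = nrow(sources),
                 profiles_extracted = sum(ok),
                 profiles_out_of_bounds = sum(!ok),
                 distances_valid = n_valid,
                 distances_kept = sum(kept),
                 distances_discarded = n_valid - sum(kept))
  structure(list(distances = distances_df, histogram = hist, fit = fit,
                 per_line_average_profiles = avgs$per_line,
                 image_average_profile = avgs$overall,
                 counts = counts, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d lines, %d kept / %d valid distances\n",
              x$counts$lines_traced, x$counts$distances_kept,
              x$counts$distances_valid))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
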
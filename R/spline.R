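#' Fit a smooth parametric centerline spline to a traced line
#'
#' Both physical coordinates are fitted as cubic (smoothing) splines of the
#' normalized cumulative chord length, giving a parametric curve
#' `t in [0, 1] -> (x_nm, y_nm)` with continuous unit tangents. With
#' `smoothing = 0` the spline interpolates the pixel coordinates exactly;
#' positive values smooth pixel-level jitter of the skeleton.
#'
#' @param line n x 2 integer matrix of (row, col) coordinates (n >= 4),
#'   ordered along the line, as returned by [trace_lines()].
#' @param smoothing smoothing parameter; `spar` of [stats::smooth.spline()]
#'   (0 = exact interpolation).
#' @param pixel_size_nm physical pixel size in nm.
#' @return object of class `center_spline` with elements `evaluate(t)`
#'   (n x 2 matrix of nm positions), `tangent(t)` (unit vectors),
#'   `n_samples`, `arc_length_nm` and `residual_rms_px`.
#' @export
fit_center_spline <- function(line, smoothing = 0, pixel_size_nm = 1) {
  if (!is.matrix(line) || nrow(line) < 4L)
    stop("line must have at least 4 coordinates")
  x <- (line[, 2L] - 1) * pixel_size_nm  # col -> x
  y <- (line[, 1L] - 1) * pixel_size_nm  # row -> y
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  if (s[length(s)] <= 0) stop("degenerate line (zero length)")
  tt <- s / s[length(s)]

  make_fit <- function(v) {
    if (smoothing <= 0) {
      f <- stats::splinefun(tt, v, method = "natural")
      list(value = f, deriv = function(t) f(t, deriv = 1L))
    } else {
      sm <- stats::smooth.spline(tt, v, spar = smoothing)
      list(value = function(t) stats::predict(sm, t)$y,
           deriv = function(t) stats::predict(sm, t, deriv = 1L)$y)
    }
  }
  fx <- make_fit(x)
  fy <- make_fit(y)

  evaluate <- function(t) cbind(x_nm = fx$value(t), y_nm = fy$value(t))
  tangent <- function(t) {
    d <- cbind(fx$deriv(t), fy$deriv(t))
    nrm <- sqrt(rowSums(d^2))
    nrm[nrm == 0] <- 1
    d / nrm
  }
  res <- evaluate(tt)
  residual_rms_px <- sqrt(mean(((res[, 1L] - x)^2 + (res[, 2L] - y)^2))) /
    pixel_size_nm
  # arc length from a dense polyline
  dense <- evaluate(seq(0, 1, length.out = 10L * nrow(line)))
  arc <- sum(sqrt(rowSums(diff(dense)^2)))
  structure(list(evaluate = evaluate, tangent = tangent,
                 n_samples = nrow(line), arc_length_nm = arc,
                 residual_rms_px = residual_rms_px,
                 pixel_size_nm = pixel_size_nm),
            class = "center_spline")
}

#' @export
print.center_spline <- function(x, ...) {
  cat(sprintf("<center_spline> %d px, %.0f nm arc, residual RMS %.2f px\n",
              x$n_samples, x$arc_length_nm, x$residual_rms_px))
  invisible(x)
}

# segmentation chain shared by both modes: blur -> otsu -> skeleton ->
# trace -> splines
segment_to_splines <- function(image, blur_sigma_px, config) {
  blurred <- gaussian_blur(image, blur_sigma_px)
  mask <- otsu_binarize(blurred)
  if (sum(mask) == 0L)
    stop_analysis("no foreground after thresholding")
  skel <- skeletonize_mask(mask)
  lines <- trace_lines(skel, config$breakpoint_angle_deg,
                       config$min_line_length_px)
  splines <- lapply(Filter(function(l) nrow(l) >= 4L, lines),
                    fit_center_spline,
                    smoothing = config$spline_smoothing,
                    pixel_size_nm = image$pixel_size_nm)
  if (length(splines) == 0L)
    stop_analysis("no traceable centerline found")
  splines
}

#' Estimate the structure midline from the axis channel alone
#'
#' One-channel mode: without a central-element channel the midline between
#' the two strands is recovered as the local transverse intensity center of
#' mass. The axis channel is blurred with
#' `sigma = max_distance_nm / (2 * pixel_size_nm)` so the two strands merge
#' into a single ridge, then binarized, skeletonized, traced and
#' spline-fitted like any guide channel.
#'
#' @param axis_image the axis-protein [channel_image()].
#' @param config a [pipeline_config()].
#' @return list of `center_spline` objects approximating the midline.
#' @export
estimate_axis_one_channel <- function(axis_image, config = pipeline_config()) {
  sigma <- config$max_distance_nm / (2 * axis_image$pixel_size_nm)
  segment_to_splines(axis_image, sigma, config)
}
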
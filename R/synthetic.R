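#' Specification of a ground-truth validation helix
#'
#' Parameters of a twisted two-strand filament whose maximum-intensity
#' projection follows `y = +/- (a/2) cos(b x)` about the midline, so the
#' maximum center-to-center strand separation equals `a`. The defaults
#' reproduce the validation condition: `a = 800` nm, `b = 1/1612` per nm,
#' rendered at a pixel size of 32.24 nm with a ~40 nm Gaussian PSF over
#' three full periods.
#'
#' @param a_nm maximum center-to-center strand separation (nm).
#' @param b_per_nm angular frequency of the twist (1/nm).
#' @param length_nm extent along the axis; default three periods.
#' @param pixel_size_nm rendered pixel size (nm); must not exceed `a_nm/4`.
#' @param psf_sigma_nm Gaussian PSF standard deviation (nm); 0 disables.
#' @param amplitude peak intensity of the noiseless render.
#' @param background constant background level.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param margin_nm transverse clearance beyond the strands on each side
#'   (room for full-length perpendicular profiles).
#' @param seed integer seed for the noise.
#' @return list of class `helix_spec`.
#' @export
helix_spec <- function(a_nm = 800, b_per_nm = 1 / 1612,
                       length_nm = 3 * 2 * pi / b_per_nm,
                       pixel_size_nm = 32.24, psf_sigma_nm = 40,
                       amplitude = 1, background = 0, noise_sd = 0,
                       margin_nm = 1100, seed = 1L) {
  stopifnot(a_nm > 0, b_per_nm > 0, pixel_size_nm > 0, psf_sigma_nm >= 0,
            background >= 0, noise_sd >= 0, amplitude > 0)
  if (length_nm <= 2 * pi / b_per_nm)
    stop("length_nm must exceed one period (2*pi/b)")
  if (pixel_size_nm > a_nm / 4)
    stop("undersampled: pixel size exceeds a_nm/4")
  structure(list(a_nm = a_nm, b_per_nm = b_per_nm, length_nm = length_nm,
                 pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 amplitude = amplitude, background = background,
                 noise_sd = noise_sd, margin_nm = margin_nm,
                 seed = as.integer(seed)),
            class = "helix_spec")
}

# deposit curve samples (x_nm, y_nm) with weights into an nr x nc grid by
# bilinear splatting; 0-based pixel centers at index * px
splat_curve <- function(x_nm, y_nm, w, nr, nc, px) {
  cx <- x_nm / px
  cy <- y_nm / px
  ok <- cx >= 0 & cx <= nc - 1 & cy >= 0 & cy <= nr - 1
  cx <- cx[ok]; cy <- cy[ok]; w <- w[ok]
  j0 <- pmin(floor(cx), nc - 2); i0 <- pmin(floor(cy), nr - 2)
  fx <- cx - j0; fy <- cy - i0
  i <- c(i0, i0, i0 + 1, i0 + 1) + 1L
  j <- c(j0, j0 + 1, j0, j0 + 1) + 1L
  vals <- c(w * (1 - fx) * (1 - fy), w * fx * (1 - fy),
            w * (1 - fx) * fy, w * fx * fy)
  as.matrix(Matrix::sparseMatrix(i = i, j = j, x = vals, dims = c(nr, nc)))
}

# arc-length sampled deposition of y(x): equal intensity per unit curve
# length, sampled densely enough (pixel/4 arc steps) to avoid aliasing
curve_samples <- function(fy, length_nm, px) {
  xs <- seq(0, length_nm, by = px / 8)
  ys <- fy(xs)
  ds <- sqrt(diff(xs)^2 + diff(ys)^2)
  list(x = (xs[-1L] + xs[-length(xs)]) / 2,
       y = (ys[-1L] + ys[-length(ys)]) / 2,
       w = ds)
}

finish_render <- function(img, spec) {
  if (spec$psf_sigma_nm > 0)
    img <- gaussian_blur(img, spec$psf_sigma_nm / spec$pixel_size_nm)
  img <- img / max(img) * spec$amplitude + spec$background
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
  pmax(img, 0)
}

#' Render the ground-truth validation helix
#'
#' Draws the two strands `y = +/- (a/2) cos(b x)` as unit-intensity curves
#' (arc-length parameterized bilinear splatting), convolves with a Gaussian
#' PSF, and adds background and optional seeded noise. A second channel
#' holds a single ridge on the midline, emulating a central-element label.
#'
#' @param spec a [helix_spec()].
#' @return list with `axis` and `central` [channel_image()]s and `truth`
#'   (ground-truth record: `a_nm`, `midline_y_nm`, `strand_y` functions,
#'   `crossings_x_nm`, `n_lobes`).
#' @export
render_helix <- function(spec = helix_spec()) {
  stopifnot(inherits(spec, "helix_spec"))
  px <- spec$pixel_size_nm
  nc <- ceiling(spec$length_nm / px) + 1L
  half_nm <- spec$a_nm / 2 + 3 * spec$psf_sigma_nm + spec$margin_nm
  half_px <- ceiling(half_nm / px)
  nr <- 2L * half_px + 1L
  mid_y <- half_px * px  # midline in nm (0-based row half_px)

  y1 <- function(x) mid_y + spec$a_nm / 2 * cos(spec$b_per_nm * x)
  y2 <- function(x) mid_y - spec$a_nm / 2 * cos(spec$b_per_nm * x)
  set.seed(spec$seed)
  s1 <- curve_samples(y1, spec$length_nm, px)
  s2 <- curve_samples(y2, spec$length_nm, px)
  axis_img <- splat_curve(c(s1$x, s2$x), c(s1$y, s2$y), c(s1$w, s2$w),
                          nr, nc, px)
  axis_img <- finish_render(axis_img, spec)
  sc <- curve_samples(function(x) rep(mid_y, length(x)), spec$length_nm, px)
  central_img <- finish_render(splat_curve(sc$x, sc$y, sc$w, nr, nc, px), spec)

  k <- 0:floor(spec$length_nm * spec$b_per_nm / pi)
  crossings <- (k + 0.5) * pi / spec$b_per_nm
  crossings <- crossings[crossings <= spec$length_nm]
  truth <- list(a_nm = spec$a_nm, b_per_nm = spec$b_per_nm,
                midline_y_nm = mid_y, midline_row = half_px + 1L,
                strand_y = list(y1, y2), crossings_x_nm = crossings,
                n_lobes = floor(spec$length_nm * spec$b_per_nm / pi))
  list(axis = channel_image(axis_img, px, role = "axis"),
       central = channel_image(central_img, px, role = "central"),
       truth = truth)
}

#' Render two straight parallel Gaussian ridges
#'
#' Oracle fixture: two horizontal ridges at `+/- separation/2` about the
#' image midline, with known ground-truth separation.
#'
#' @param separation_nm center-to-center ridge distance (> 2 pixels).
#' @param length_nm ridge length along the axis.
#' @param pixel_size_nm rendered pixel size (nm).
#' @param psf_sigma_nm Gaussian PSF sigma (nm); 0 gives single-pixel ridges.
#' @param margin_nm transverse clearance on each side.
#' @return a [channel_image()] with attribute `truth` (separation and
#'   midline position).
#' @export
render_parallel_ridges <- function(separation_nm, length_nm = 10000,
                                   pixel_size_nm = 32.24, psf_sigma_nm = 40,
                                   margin_nm = 1100) {
  stopifnot(length_nm > 0, pixel_size_nm > 0, psf_sigma_nm >= 0)
  if (separation_nm <= 2 * pixel_size_nm)
    stop("degenerate separation: must exceed two pixels")
  px <- pixel_size_nm
  nc <- ceiling(length_nm / px) + 1L
  half_px <- ceiling((separation_nm / 2 + 3 * psf_sigma_nm + margin_nm) / px)
  nr <- 2L * half_px + 1L
  mid_y <- half_px * px
  spec <- list(psf_sigma_nm = psf_sigma_nm, pixel_size_nm = px,
               amplitude = 1, background = 0, noise_sd = 0)
  s1 <- curve_samples(function(x) rep(mid_y + separation_nm / 2, length(x)),
                      length_nm, px)
  s2 <- curve_samples(function(x) rep(mid_y - separation_nm / 2, length(x)),
                      length_nm, px)
  img <- splat_curve(c(s1$x, s2$x), c(s1$y, s2$y), c(s1$w, s2$w), nr, nc, px)
  img <- finish_render(img, spec)
  out <- channel_image(img, px, role = "axis")
  attr(out, "truth") <- list(separation_nm = separation_nm, midline_y_nm = mid_y)
  out
}

#' Deterministic binary shape fixtures
#'
#' Small binary masks (ring, open "C", L, T, bar) used to exercise
#' skeletonization, line tracing and enclosed-region detection.
#'
#' @param kind shape name.
#' @param canvas optional `c(nrow, ncol)`; defaults to a canvas that fits
#'   the shape with a 3-pixel margin.
#' @param outer_r,inner_r ring radii in pixels (ring / open_c).
#' @param gap_frac fraction of the full circle removed from an open "C".
#' @param arm_px arm length for L and T.
#' @param thickness_px line thickness for L and T.
#' @param bar_width_px,bar_length_px bar dimensions.
#' @return 0/1 integer matrix.
#' @export
render_shape <- function(kind = c("ring", "open_c", "L", "T", "bar"),
                         canvas = NULL, outer_r = 30, inner_r = 20,
                         gap_frac = 0.2, arm_px = 40, thickness_px = 1,
                         bar_width_px = 5, bar_length_px = 50) {
  kind <- match.arg(kind)
  need <- switch(kind,
    ring = , open_c = c(2 * outer_r + 7, 2 * outer_r + 7),
    L = , T = c(arm_px + 6, arm_px + 6),
    bar = c(bar_width_px + 6, bar_length_px + 6))
  if (is.null(canvas)) canvas <- need
  if (any(canvas < need)) stop("shape exceeds canvas")
  nr <- canvas[1L]; nc <- canvas[2L]
  m <- matrix(0L, nr, nc)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  if (kind %in% c("ring", "open_c")) {
    stopifnot(inner_r < outer_r)
    ij <- expand.grid(i = 1:nr, j = 1:nc)
    r <- sqrt((ij$i - cr)^2 + (ij$j - cc)^2)
    sel <- r >= inner_r & r <= outer_r
    if (kind == "open_c") {
      th <- atan2(ij$i - cr, ij$j - cc)  # gap centered on the +x direction
      sel <- sel & abs(th) > gap_frac * pi
    }
    m[cbind(ij$i[sel], ij$j[sel])] <- 1L
  } else if (kind == "L") {
    r0 <- floor(cr - arm_px / 2); c0 <- floor(cc - arm_px / 2)
    m[r0:(r0 + arm_px - 1L), c0:(c0 + thickness_px - 1L)] <- 1L
    m[(r0 + arm_px - thickness_px):(r0 + arm_px - 1L),
      c0:(c0 + arm_px - 1L)] <- 1L
  } else if (kind == "T") {
    r0 <- floor(cr - arm_px / 2); c0 <- floor(cc - arm_px / 2)
    m[r0:(r0 + thickness_px - 1L), c0:(c0 + arm_px - 1L)] <- 1L
    cmid <- floor(cc)
    m[r0:(r0 + arm_px - 1L), cmid:(cmid + thickness_px - 1L)] <- 1L
  } else {
    r0 <- floor(cr - bar_width_px / 2); c0 <- floor(cc - bar_length_px / 2)
    m[r0:(r0 + bar_width_px - 1L), c0:(c0 + bar_length_px - 1L)] <- 1L
  }
  structure(m, class = c("binary_mask", class(m)))
}
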
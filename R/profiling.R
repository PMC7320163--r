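#' Find regions enclosed by foreground shapes
#'
#' Flood-fills the background from the image border (4-connectivity) and
#' returns the background pixels that were not reached, i.e. the areas
#' embedded in closed shapes. Applied to the binarized axis channel this
#' marks the in-plane "frontal view" lobes of the twisted two-strand
#' structure, where the strand separation is maximal.
#'
#' @param axis_mask 0/1 matrix.
#' @return 0/1 matrix marking enclosed background pixels.
#' @export
find_enclosed_regions <- function(axis_mask) {
  m <- as_mask(axis_mask)
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  filled <- EBImage::floodFill(p, c(1L, 1L), col = 2L)
  filled <- matrix(as.integer(filled), nr + 2L, nc + 2L)
  enc <- (filled == 0L)[2:(nr + 1L), 2:(nc + 1L)]
  out <- matrix(as.integer(enc), nr, nc)
  structure(out, class = c("binary_mask", class(out)))
}

#' Place profile source points on splines inside enclosed regions
#'
#' Samples each spline at one point per pixel-equivalent arc step and keeps
#' the samples whose nearest pixel lies inside an enclosed region (the
#' logical AND of line coordinates and flood-fill image). Each source
#' carries the local unit normal (tangent rotated +90 degrees).
#'
#' @param splines list of `center_spline` objects.
#' @param enclosed 0/1 matrix from [find_enclosed_regions()], or `NULL` to
#'   keep all spline samples (used for structures that enclose nothing).
#' @param pixel_size_nm physical pixel size in nm.
#' @return data.frame with columns `line_id`, `t`, `x_nm`, `y_nm`,
#'   `normal_x`, `normal_y`.
#' @export
select_sources <- function(splines, enclosed, pixel_size_nm) {
  if (length(splines) == 0L) stop("splines must be non-empty")
  out <- lapply(seq_along(splines), function(li) {
    sp <- splines[[li]]
    n <- max(2L, round(sp$arc_length_nm / pixel_size_nm))
    ts <- seq(0, 1, length.out = n)
    pos <- sp$evaluate(ts)
    tan <- sp$tangent(ts)
    keep <- rep(TRUE, n)
    if (!is.null(enclosed)) {
      m <- as_mask(enclosed)
      i <- round(pos[, 2L] / pixel_size_nm) + 1L  # row from y
      j <- round(pos[, 1L] / pixel_size_nm) + 1L  # col from x
      inside <- i >= 1L & i <= nrow(m) & j >= 1L & j <= ncol(m)
      keep <- inside
      keep[inside] <- m[cbind(i[inside], j[inside])] == 1L
    }
    data.frame(line_id = rep(li, sum(keep)), t = ts[keep],
               x_nm = pos[keep, 1L], y_nm = pos[keep, 2L],
               normal_x = -tan[keep, 2L], normal_y = tan[keep, 1L])
  })
  do.call(rbind, out)
}

# vectorized bilinear interpolation at fractional 0-based pixel coords;
# NA outside the grid
bilinear_sample <- function(m, cx, cy) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- cx >= 0 & cx <= nc - 1 & cy >= 0 & cy <= nr - 1
  out <- rep(NA_real_, length(cx))
  if (!any(ok)) return(out)
  cx <- cx[ok]; cy <- cy[ok]
  j0 <- pmin(floor(cx), nc - 2); i0 <- pmin(floor(cy), nr - 2)
  fx <- cx - j0; fy <- cy - i0
  i0 <- i0 + 1L; j0 <- j0 + 1L  # to 1-based
  v <- m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
       m[cbind(i0, j0 + 1L)] * fx * (1 - fy) +
       m[cbind(i0 + 1L, j0)] * (1 - fx) * fy +
       m[cbind(i0 + 1L, j0 + 1L)] * fx * fy
  out[ok] <- v
  out
}

# Catmull-Rom cubic interpolation (separable, edge-replicated stencil).
# Bilinear interpolation is piecewise linear, so interpolated maxima lock
# onto pixel knots and bias sub-pixel peak refinement inward by up to half
# a pixel; the C1-continuous cubic removes that quantization.
cubic_sample <- function(m, cx, cy) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- cx >= 0 & cx <= nc - 1 & cy >= 0 & cy <= nr - 1
  out <- rep(NA_real_, length(cx))
  if (!any(ok)) return(out)
  cx <- cx[ok]; cy <- cy[ok]
  j0 <- pmin(pmax(floor(cx), 0), nc - 2)
  i0 <- pmin(pmax(floor(cy), 0), nr - 2)
  wts <- function(f) {
    cbind(((-0.5 * f + 1) * f - 0.5) * f,
          (1.5 * f - 2.5) * f * f + 1,
          ((-1.5 * f + 2) * f + 0.5) * f,
          (0.5 * f - 0.5) * f * f)
  }
  wx <- wts(cx - j0)
  wy <- wts(cy - i0)
  v <- 0
  for (a in 0:3) {
    ii <- pmin(pmax(i0 - 1L + a, 0L), nr - 1L) + 1L
    for (b in 0:3) {
      jj <- pmin(pmax(j0 - 1L + b, 0L), nc - 1L) + 1L
      v <- v + m[cbind(ii, jj)] * wy[, a + 1L] * wx[, b + 1L]
    }
  }
  out[ok] <- v
  out
}

interp_sample <- function(m, cx, cy, interp = "cubic") {
  if (identical(interp, "bilinear")) bilinear_sample(m, cx, cy)
  else cubic_sample(m, cx, cy)
}

profile_offsets <- function(halflength_nm, step_nm) {
  k <- floor(halflength_nm / step_nm)
  seq(-k, k) * step_nm  # odd length, 0 present
}

#' Extract a perpendicular cross-sectional intensity profile
#'
#' Samples the axis channel along the source normal at uniform offsets
#' `-H..H` nm, by Catmull-Rom cubic interpolation (default) or bilinear
#' (`config$profile_interp`). Profiles whose sampling segment leaves the
#' image are rejected rather than zero-padded, since padding would bias
#' peak detection.
#'
#' @param axis_image [channel_image()] to sample (typically lightly blurred).
#' @param source one row of the [select_sources()] data.frame (list-like
#'   with `x_nm`, `y_nm`, `normal_x`, `normal_y`).
#' @param config a [pipeline_config()].
#' @return list with `offsets_nm`, `intensities`, `source` and `ok`;
#'   `ok = FALSE` with `reason = "out_of_bounds"` when the segment leaves
#'   the image.
#' @export
extract_profile <- function(axis_image, source, config = pipeline_config()) {
  px <- axis_image$pixel_size_nm
  step <- resolved_step_nm(config, px)
  offs <- profile_offsets(config$profile_halflength_nm, step)
  cx <- (source$x_nm + offs * source$normal_x) / px
  cy <- (source$y_nm + offs * source$normal_y) / px
  vals <- interp_sample(axis_image$pixels, cx, cy, config$profile_interp)
  if (anyNA(vals))
    return(list(offsets_nm = offs, intensities = NULL, source = source,
                ok = FALSE, reason = "out_of_bounds"))
  list(offsets_nm = offs, intensities = vals, source = source, ok = TRUE,
       reason = "ok")
}

# 3-point parabolic refinement around sample i; returns refined offset
refine_peak <- function(offs, y, i) {
  if (i <= 1L || i >= length(y)) return(offs[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom >= 0) return(offs[i])
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  offs[i] + delta * (offs[2L] - offs[1L])
}

local_maxima <- function(y) {
  # strict local maxima with plateau handling (center of plateau)
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[j]) idx <- c(idx, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

#' Peak-to-peak distance of a bimodal cross-sectional profile
#'
#' Identifies the strongest local maximum on each side of the spline
#' (offset 0), refines both peak positions by a 3-point parabolic fit, and
#' reports their separation. Profiles lacking a local maximum on either
#' side are reported as non-bimodal. Requiring one peak per side (rather
#' than the two tallest overall) exploits that the spline runs between the
#' strands, and prevents locking onto a double peak of a single strand.
#'
#' @param profile as returned by [extract_profile()].
#' @return list with `distance_nm`, `center_nm` (midpoint between the two
#'   refined peaks), `kept` (`NA`, set by [filter_distances()]) and `reason`.
#' @export
peak_to_peak_distance <- function(profile) {
  if (!isTRUE(profile$ok))
    return(list(distance_nm = NA_real_, center_nm = NA_real_, kept = FALSE,
                reason = profile$reason))
  offs <- profile$offsets_nm
  y <- profile$intensities
  peaks <- local_maxima(y)
  left <- peaks[offs[peaks] < 0]
  right <- peaks[offs[peaks] > 0]
  if (length(left) == 0L || length(right) == 0L)
    return(list(distance_nm = NA_real_, center_nm = NA_real_, kept = FALSE,
                reason = "no_bimodal"))
  pick <- function(cand) {
    o <- order(-y[cand], abs(offs[cand]))
    cand[o[1L]]
  }
  li <- pick(left); ri <- pick(right)
  lo <- refine_peak(offs, y, li)
  ro <- refine_peak(offs, y, ri)
  list(distance_nm = ro - lo, center_nm = (ro + lo) / 2, kept = NA,
       reason = "unfiltered")
}

#' Apply the distance bounds filter
#'
#' Flags each measured distance as kept when it lies within
#' `[min_distance_nm, max_distance_nm]`; out-of-bounds distances are
#' retained with their reason (`below_min` / `above_max`), never deleted,
#' so counts remain auditable. The default 400-1200 nm bounds exclude
#' undesired structures such as two strands lying close together.
#'
#' @param distances list of results from [peak_to_peak_distance()].
#' @param config a [pipeline_config()].
#' @return the same list with `kept` and `reason` finalized.
#' @export
filter_distances <- function(distances, config = pipeline_config()) {
  lapply(distances, function(d) {
    if (!is.na(d$distance_nm) && d$reason %in% c("unfiltered", "kept",
                                                 "below_min", "above_max")) {
      if (d$distance_nm < config$min_distance_nm) {
        d$kept <- FALSE; d$reason <- "below_min"
      } else if (d$distance_nm > config$max_distance_nm) {
        d$kept <- FALSE; d$reason <- "above_max"
      } else {
        d$kept <- TRUE; d$reason <- "kept"
      }
    } else {
      d$kept <- FALSE
    }
    d
  })
}

#' Align kept profiles at their peak-pair center and average
#'
#' Each kept profile is shifted (by linear interpolation onto the common
#' offset grid) so the midpoint between its two peaks sits at offset 0;
#' aligned profiles are then averaged per line and over the whole image.
#'
#' @param profiles list of profiles from [extract_profile()].
#' @param distances matching list from [filter_distances()].
#' @return list with `per_line` (named list of average profiles) and
#'   `overall` (grand average); each average is a list with `offsets_nm`,
#'   `intensities`, `n` and `source = "average"`.
#' @export
align_and_average <- function(profiles, distances) {
  stopifnot(length(profiles) == length(distances))
  kept <- vapply(distances, function(d) isTRUE(d$kept), logical(1L))
  if (!any(kept)) stop_analysis("nothing to average")
  offs <- profiles[[which(kept)[1L]]]$offsets_nm
  aligned <- list()
  line_ids <- integer(0)
  for (i in which(kept)) {
    p <- profiles[[i]]
    sh <- stats::approx(p$offsets_nm - distances[[i]]$center_nm,
                        p$intensities, xout = offs, rule = 2L)$y
    aligned[[length(aligned) + 1L]] <- sh
    line_ids <- c(line_ids, as.integer(p$source$line_id))
  }
  mat <- do.call(rbind, aligned)
  avg_of <- function(rows) list(offsets_nm = offs,
                                intensities = colMeans(mat[rows, , drop = FALSE]),
                                n = length(rows), source = "average")
  per_line <- lapply(split(seq_along(line_ids), line_ids), avg_of)
  list(per_line = per_line, overall = avg_of(seq_along(line_ids)))
}
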
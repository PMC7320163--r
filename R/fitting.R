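#' Histogram of kept peak-to-peak distances
#'
#' Uniform half-open bins `[lo, hi)`; distances outside the range are
#' excluded (they have normally been filtered already).
#'
#' @param distances numeric vector of distances in nm.
#' @param bin_nm bin width (> 0).
#' @param range length-2 numeric `(lo, hi)`.
#' @return list of class `distance_histogram` with `bin_edges_nm`, `counts`
#'   and `bin_nm`.
#' @export
histogram_distances <- function(distances, bin_nm, range) {
  if (length(distances) == 0L) stop("empty distance list")
  stopifnot(bin_nm > 0, length(range) == 2L, range[2L] > range[1L])
  lo <- range[1L]
  nbin <- ceiling((range[2L] - lo) / bin_nm - 1e-9)
  edges <- lo + (0:nbin) * bin_nm
  idx <- floor((distances - lo) / bin_nm) + 1L
  inb <- idx >= 1L & idx <= nbin
  counts <- tabulate(idx[inb], nbins = nbin)
  structure(list(bin_edges_nm = edges, counts = counts, bin_nm = bin_nm),
            class = "distance_histogram")
}

#' Half-normal cutoff model for distance histograms
#'
#' Projection onto 2D can only underestimate the strand separation, so the
#' distance histogram rises toward the true separation `c` and is empty
#' above it. The model is a half-Gaussian with support below the cutoff:
#' `y(x) = A exp(-(x - c)^2 / (2 sigma^2)) + n` for `x <= c` and `y(x) = 0`
#' for `x > c`. The center `c` is the reported strand distance.
#'
#' @param x positions (nm).
#' @param A,c,sigma,n amplitude, cutoff center, spread, noise floor.
#' @return model values.
#' @export
half_norm_model <- function(x, A, c, sigma, n) {
  ifelse(x <= c, A * exp(-(x - c)^2 / (2 * sigma^2)) + n, 0)
}

# mean model value over bins [e1, e2): the Gaussian-plus-floor mass below
# the cutoff divided by bin width, so a cutoff inside a bin contributes the
# partial integral. Regressors for A and n separately (the model is linear
# in both given c and sigma).
.halfnorm_regressors <- function(e1, e2, cc, sigma) {
  hi <- pmin(e2, cc)
  open_len <- pmax(hi - e1, 0)
  g <- sigma * sqrt(2 * pi) *
    (stats::pnorm((hi - cc) / sigma) - stats::pnorm((e1 - cc) / sigma))
  g[open_len <= 0] <- 0
  cbind(A = g / (e2 - e1), n = open_len / (e2 - e1))
}

# given c and sigma, solve A and n by linear least squares against the
# bin-averaged counts (nonnegativity by clamping); returns window SSE
.halfnorm_inner <- function(e1, e2, counts, cc, sigma) {
  X <- .halfnorm_regressors(e1, e2, cc, sigma)
  act <- X[, 2L] > 0
  sse_above <- sum(counts[!act]^2)  # model is identically 0 there
  Xa <- X[act, , drop = FALSE]; yb <- counts[act]
  if (length(yb) == 0L) return(list(sse = sse_above, A = 0, n = 0))
  fit_with <- function(cols) {
    cf <- tryCatch(qr.coef(qr(Xa[, cols, drop = FALSE]), yb),
                   error = function(e) NULL)
    if (is.null(cf) || anyNA(cf) || any(cf < 0)) return(NULL)
    full <- c(A = 0, n = 0); full[cols] <- cf
    list(sse = sum((yb - Xa %*% full)^2), A = unname(full[1L]),
         n = unname(full[2L]))
  }
  sol <- if (length(yb) >= 2L) fit_with(1:2) else NULL
  if (is.null(sol)) sol <- fit_with(1L)
  if (is.null(sol)) sol <- fit_with(2L)
  if (is.null(sol)) sol <- list(sse = sum(yb^2), A = 0, n = 0)
  sol$sse <- sol$sse + sse_above
  sol
}

# profile SSE over (sigma | c): 1-D minimization
.halfnorm_profile_c <- function(e1, e2, counts, cc, bin_nm, span,
                                tol = 1e-8) {
  obj <- function(lsig) .halfnorm_inner(e1, e2, counts, cc, exp(lsig))$sse
  opt <- stats::optimize(obj, interval = log(c(bin_nm / 4, 4 * span)),
                         tol = tol)
  sigma <- exp(opt$minimum)
  sol <- .halfnorm_inner(e1, e2, counts, cc, sigma)
  list(sse = sol$sse, A = sol$A, n = sol$n, sigma = sigma)
}

#' Fit the half-normal cutoff model to a distance histogram
#'
#' Least-squares fit of [half_norm_model()] to the histogram counts. Each
#' bin is compared against the model's mean over that bin (its integral
#' divided by the bin width), so a cutoff lying inside a bin contributes
#' exactly its partial mass; this localizes `c` continuously within a bin,
#' which fitting bin centers pointwise cannot do. The cutoff makes the
#' residuals discontinuous in `c`, so derivative-based optimizers cannot
#' move `c` reliably; the fit is instead profiled: a grid plus
#' golden-section search over `c`, with `sigma` minimized one-dimensionally
#' and `(A, n)` solved linearly (variable projection) at each candidate. The fitted center `c` is the reported
#' strand distance; its standard error comes from the curvature of the
#' profile SSE at the optimum.
#'
#' @param hist a [histogram_distances()] result.
#' @param fit_window_nm numeric `(lo, hi)` restricting the bins entering
#'   the fit, or `NULL` for the full histogram range (default; the noise
#'   floor `n` absorbs the far tail).
#' @return list of class `half_norm_fit` with `A`, `c`, `sigma`, `n`,
#'   `c_stderr`, `converged` and `fit_window_nm`.
#' @export
fit_half_norm <- function(hist, fit_window_nm = NULL) {
  edges <- hist$bin_edges_nm
  counts <- hist$counts
  bin_nm <- hist$bin_nm
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  if (sum(counts > 0) < 5L) stop("too few non-empty bins (need >= 5)")
  if (is.null(fit_window_nm))
    fit_window_nm <- c(edges[1L], edges[length(edges)])
  inw <- centers >= fit_window_nm[1L] & centers <= fit_window_nm[2L]
  e1 <- edges[-length(edges)][inw]; e2 <- edges[-1L][inw]
  yw <- counts[inw]
  if (length(yw) < 4L) stop("fit window contains too few bins")
  span <- max(e2) - min(e1)
  nz <- which(yw > 0)
  data_span <- c(e1[nz[1L]], e2[nz[length(nz)]] + bin_nm)

  prof <- function(cc, tol = 1e-8) .halfnorm_profile_c(e1, e2, yw, cc,
                                                       bin_nm, span, tol)
  # coarse grid over c, then golden-section refinement between neighbors
  grid <- seq(max(fit_window_nm[1L], data_span[1L]),
              min(fit_window_nm[2L], data_span[2L]), by = bin_nm / 2)
  sse_grid <- vapply(grid, function(cc) prof(cc)$sse, numeric(1L))
  i0 <- which.min(sse_grid)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(function(cc) prof(cc)$sse, interval = c(lo, hi),
                         tol = 1e-8)
  cand <- if (opt$objective <= sse_grid[i0]) opt$minimum else grid[i0]
  best <- prof(cand, tol = 1e-10)
  c_hat <- cand

  # stderr of c from profile-SSE curvature: var(c) ~ 2 s^2 / SSE''(c)
  m <- length(yw)
  s2 <- best$sse / max(1L, m - 4L)
  h <- bin_nm / 10
  sse_m <- prof(max(data_span[1L], c_hat - h))$sse
  sse_p <- prof(min(data_span[2L], c_hat + h))$sse
  curv <- (sse_m - 2 * best$sse + sse_p) / h^2
  c_stderr <- if (is.finite(curv) && curv > 0) sqrt(2 * s2 / curv) else NA_real_

  converged <- is.finite(best$sse) && best$A > 0 && best$sigma > 0 &&
    c_hat >= data_span[1L] && c_hat <= data_span[2L]
  structure(list(A = best$A, c = c_hat, sigma = best$sigma, n = best$n,
                 c_stderr = c_stderr, converged = converged,
                 fit_window_nm = fit_window_nm, sse = best$sse),
            class = "half_norm_fit")
}

#' @export
print.half_norm_fit <- function(x, ...) {
  cat(sprintf(
    "<half_norm_fit> c = %.2f nm (stderr %.2f), sigma = %.2f, A = %.3g, n = %.3g, converged = %s\n",
    x$c, x$c_stderr, x$sigma, x$A, x$n, x$converged))
  invisible(x)
}

# prominence of each local maximum: height minus the highest saddle
# separating it from a taller peak (tallest peak: height minus global min)
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    taller <- peaks[y[peaks] > h]
    if (length(taller) == 0L) return(h - min(y))
    saddle <- -Inf
    for (q in taller) {
      rng <- if (q < p) q:p else p:q
      saddle <- max(saddle, min(y[rng]))
    }
    h - saddle
  }, numeric(1L))
}

#' Single-Gaussian fit of a monomodal profile
#'
#' Fits `offset + amplitude * exp(-(x - mean)^2 / (2 sd^2))` by nonlinear
#' least squares and reports the width both as the standard deviation and
#' as the full width at half maximum (`2 sqrt(2 ln 2) * sd`). Used for
#' monomodally distributed proteins such as central-element components.
#'
#' @param profile a profile list with `offsets_nm` and `intensities` (e.g.
#'   from [extract_profile()] or [align_and_average()]).
#' @return list of class `gaussian_fit` with `amplitude`, `mean_nm`,
#'   `sd_nm`, `offset` and `fwhm_nm`.
#' @export
fit_gaussian_profile <- function(profile) {
  x <- profile$offsets_nm
  y <- profile$intensities
  if (is.null(y) || length(y) < 5L) stop("profile too short")
  peaks <- local_maxima(y)
  if (length(peaks) >= 2L) {
    prom <- peak_prominences(y, peaks)
    if (sum(prom > 0.2 * diff(range(y))) >= 2L)
      stop("profile not monomodal")
  }
  off0 <- min(y)
  amp0 <- max(y) - off0
  mu0 <- x[which.max(y)]
  w <- pmax(y - off0, 0)
  sd0 <- sqrt(sum(w * (x - mu0)^2) / max(sum(w), 1e-12))
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- diff(range(x)) / 10
  df <- data.frame(x = x, y = y)
  # moment-based starts, nudged off any exact solution (a zero-residual
  # start makes the Levenberg-Marquardt gradient test degenerate)
  fit <- minpack.lm::nlsLM(
    y ~ n0 + A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
    start = list(n0 = off0 + 0.05 * amp0, A = 0.9 * amp0, mu = mu0,
                 s = 1.2 * sd0),
    lower = c(0, 1e-12, min(x), 1e-6),
    upper = c(Inf, Inf, max(x), diff(range(x))),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["A"]), mean_nm = unname(cf["mu"]),
                 sd_nm = unname(cf["s"]), offset = unname(cf["n0"]),
                 fwhm_nm = 2 * sqrt(2 * log(2)) * unname(cf["s"])),
            class = "gaussian_fit")
}
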
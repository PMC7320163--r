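#' Gaussian blur with reflective boundaries
#'
#' Separable Gaussian convolution used to suppress noise and intensity
#' fluctuations before thresholding, and (with a much larger sigma) to merge
#' the two strands into a single ridge in one-channel midline estimation.
#' Boundaries are handled by mirror reflection, so total intensity of
#' structures at least 3 sigma away from the border is conserved.
#'
#' @param image a [channel_image()] or numeric matrix.
#' @param sigma_px kernel standard deviation in pixels (> 0).
#' @return same type as the input, blurred.
#' @export
gaussian_blur <- function(image, sigma_px) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || sigma_px <= 0)
    stop("sigma_px must be a single positive number")
  m <- if (inherits(image, "channel_image")) image$pixels else image
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  out <- conv_sep_reflect(m, k, r)
  if (inherits(image, "channel_image")) {
    image$pixels <- pmax(out, 0)
    image
  } else out
}

# reflect-pad then run the 1D kernel down columns, transpose, repeat
conv_sep_reflect <- function(m, k, r) {
  pad_idx <- function(n) {
    # mirror reflection without repeating the edge sample beyond need:
    # indices r..1, 1..n, n..n-r+1
    c(pmin(n, r:1), 1:n, pmax(1L, n - seq_len(r) + 1L))
  }
  one_pass <- function(x) {
    p <- x[pad_idx(nrow(x)), , drop = FALSE]
    f <- stats::filter(p, k, sides = 2L)
    matrix(f[(r + 1L):(r + nrow(x)), ], nrow = nrow(x))
  }
  t(one_pass(t(one_pass(m))))
}

#' Otsu threshold of an intensity image
#'
#' Exhaustively maximizes the between-class variance over a 256-bin
#' histogram spanning the image intensity range and returns the cut value
#' (the edge between the two classes, on the original intensity scale).
#'
#' @param x numeric matrix or vector of intensities.
#' @param levels number of histogram bins.
#' @return the threshold; pixels strictly above it form the foreground.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("degenerate intensity distribution")
  bin <- pmin(levels, pmax(1L, floor((v - lo) / (hi - lo) * levels) + 1L))
  cnt <- as.numeric(tabulate(bin, nbins = levels))
  centers <- lo + (seq_len(levels) - 0.5) * (hi - lo) / levels
  w0 <- cumsum(cnt)
  s0 <- cumsum(cnt * centers)
  tot <- w0[levels]; stot <- s0[levels]
  # candidate cuts after bin t = 1..levels-1
  w0 <- w0[-levels]; s0 <- s0[-levels]
  w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s0 / w0
  mu1 <- (stot - s0) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  t_best <- which.max(bcv)
  lo + t_best * (hi - lo) / levels  # upper edge of class-0 bins
}

#' Binarize an image by Otsu's method
#'
#' @param image a [channel_image()] or numeric matrix with at least two
#'   distinct intensity values.
#' @return an integer 0/1 matrix of the same shape (class `binary_mask`).
#' @export
otsu_binarize <- function(image) {
  m <- if (inherits(image, "channel_image")) image$pixels else image
  th <- otsu_threshold(m)
  mask <- matrix(as.integer(m > th), nrow = nrow(m))
  structure(mask, class = c("binary_mask", class(mask)))
}

as_mask <- function(m) {
  m <- unclass(m)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("mask must be strictly binary")
  m
}
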
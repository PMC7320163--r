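#' Channel image with physical pixel size
#'
#' The raster container every pipeline stage operates on: a 2D grid of
#' non-negative intensities together with the physical pixel size in
#' nanometres. Pixel centres sit at integer (0-based) grid coordinates, so a
#' pixel at 0-based `(row, col)` has physical position
#' `(x, y) = (col, row) * pixel_size_nm`.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size_nm physical edge length of one (isotropic) pixel in nm.
#' @param role one of `"axis"` (e.g. SYCP3), `"central"` (e.g. SYCE3) or
#'   `"generic"`.
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_nm, role = c("generic", "axis", "central")) {
  role <- match.arg(role)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("intensities must be finite")
  if (any(pixels < 0))
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm), role = role),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %d x %d px, %.4g nm/px, role '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$role))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

# minimum raster for full pipeline use
assert_pipeline_image <- function(img) {
  if (nrow(img$pixels) < 16L || ncol(img$pixels) < 16L)
    stop("image too small for pipeline use (needs >= 16 x 16 pixels)")
  invisible(img)
}

#' Maximum intensity projection of a z-stack
#'
#' Collapses a 3D stack to 2D by taking the per-pixel maximum over planes,
#' the standard projection applied to SIM z-stacks before profile analysis.
#'
#' @param stack a 3D numeric array (row, col, plane) or a list of matrices of
#'   identical dimensions.
#' @return a matrix with the per-pixel maximum.
#' @export
project_z <- function(stack) {
  if (is.list(stack)) {
    if (length(stack) == 0L) stop("empty stack")
    d <- dim(stack[[1L]])
    if (any(!vapply(stack, function(m) identical(dim(m), d), logical(1L))))
      stop("all planes must have identical dimensions")
    stack <- array(unlist(stack, use.names = FALSE), dim = c(d, length(stack)))
  }
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("stack must be a 3D array or list of matrices")
  if (dim(stack)[3L] < 1L) stop("empty stack")
  apply(stack, c(1L, 2L), max)
}

#' Read image channels from a TIFF file
#'
#' Reads one [channel_image()] per requested channel. Channels may be stored
#' as TIFF pages (directories) or as the third dimension of a single page;
#' both layouts are handled. The pixel size is always supplied by the caller:
#' resolution tags written by SIM reconstruction software are unreliable, so
#' when the file carries them they are ignored with a warning.
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param channel_indices 1-based channel indices to read.
#' @param pixel_size_nm physical pixel size in nm (mandatory).
#' @param role role assigned to every returned channel.
#' @return list of [channel_image()] objects, one per requested index.
#' @export
read_channels <- function(path, channel_indices, pixel_size_nm,
                          role = "generic") {
  if (!file.exists(path)) stop("file not found: ", path)
  # note: integer TIFFs come back rescaled to [0, 1]; the pipeline is
  # invariant under positive intensity scaling, so this is harmless
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attr(pages[[1L]], "info")
  if (!is.null(info) && any(c("x.resolution", "y.resolution") %in% names(info)))
    warning("TIFF resolution metadata ignored; using supplied pixel_size_nm")
  # a single page with a 3rd dimension holds channels in that dimension
  chans <- list()
  for (p in pages) {
    if (is.matrix(p)) {
      chans[[length(chans) + 1L]] <- p
    } else if (is.array(p) && length(dim(p)) == 3L) {
      for (k in seq_len(dim(p)[3L])) chans[[length(chans) + 1L]] <- p[, , k]
    } else {
      stop("non-2D TIFF page; max-project 3D stacks first (see project_z)")
    }
  }
  if (length(chans) == 0L || any(vapply(chans, length, integer(1L)) == 0L))
    stop("zero-size image")
  bad <- channel_indices < 1L | channel_indices > length(chans)
  if (any(bad))
    stop("channel index out of range (file has ", length(chans), " channels)")
  d <- dim(chans[[channel_indices[1L]]])
  out <- lapply(channel_indices, function(i) {
    m <- chans[[i]]
    if (!identical(dim(m), d)) stop("requested channels differ in shape")
    m <- matrix(as.numeric(m), nrow(m))  # drop TIFF tag attributes
    channel_image(m - min(m, 0), pixel_size_nm, role = role)
  })
  out
}

#' Write channels to a multi-page grayscale TIFF
#'
#' Intensities are rescaled to `[0, 1]` jointly over all channels and stored
#' as 32-bit float, one page per channel. The pipeline is invariant under
#' positive intensity scaling, so the rescaling is lossless for analysis.
#'
#' @param channels list of [channel_image()] or plain matrices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_channels_tiff <- function(channels, path) {
  mats <- lapply(channels, function(ch)
    if (inherits(ch, "channel_image")) ch$pixels else ch)
  hi <- max(vapply(mats, max, numeric(1L)))
  if (hi > 1) mats <- lapply(mats, function(m) m / hi)
  tiff::writeTIFF(mats, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
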
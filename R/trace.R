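#' Trace ordered centerlines from a thin skeleton
#'
#' Sorts skeleton pixels into ordered 8-connected lines. Junction pixels
#' (more than two skeleton neighbors) always break lines and belong to no
#' line; a direction change of more than `breakpoint_angle_deg` between
#' successive 5-pixel chords marks a sharp edge and starts a new line.
#' Lines shorter than `min_line_length_px` are discarded (but counted, so
#' pixel bookkeeping stays exact).
#'
#' @param skeleton 0/1 matrix as produced by [skeletonize_mask()].
#' @param breakpoint_angle_deg chord-angle threshold in degrees.
#' @param min_line_length_px minimum number of pixels in a kept line.
#' @return list of traced lines, each an n x 2 integer matrix of 1-based
#'   (row, col) coordinates, with attributes `junction_pixels` and
#'   `short_pixels` holding the counts of junction and discarded pixels.
#' @export
trace_lines <- function(skeleton, breakpoint_angle_deg = 60,
                        min_line_length_px = 10L) {
  m <- as_mask(skeleton)
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m == 1L)
  if (length(fg) == 0L)
    return(structure(list(), junction_pixels = 0L, short_pixels = 0L))

  key <- function(r, c) (c - 1L) * nr + r
  exists_px <- logical(nr * nc)
  exists_px[fg] <- TRUE
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  neighbors <- function(r, c) {
    rr <- r + offs[, 1L]; cc <- c + offs[, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    rr <- rr[ok]; cc <- cc[ok]
    keep <- exists_px[key(rr, cc)]
    cbind(rr[keep], cc[keep])
  }
  rc <- cbind((fg - 1L) %% nr + 1L, (fg - 1L) %/% nr + 1L)
  deg <- integer(length(fg))
  for (i in seq_along(fg)) deg[i] <- nrow(neighbors(rc[i, 1L], rc[i, 2L]))

  junction <- deg > 2L
  n_junction <- sum(junction)
  # junction pixels removed before walking
  exists_px[fg[junction]] <- FALSE

  visited <- logical(nr * nc)
  visited[fg[junction]] <- TRUE
  alive <- fg[!junction]

  walk_from <- function(r, c) {
    path <- matrix(0L, nrow = length(alive), ncol = 2L)
    n <- 0L
    repeat {
      n <- n + 1L
      path[n, ] <- c(r, c)
      visited[key(r, c)] <<- TRUE
      nb <- neighbors(r, c)
      nb <- nb[!visited[key(nb[, 1L], nb[, 2L])], , drop = FALSE]
      if (nrow(nb) == 0L) break
      # prefer 4-connected steps so diagonal shortcuts do not skip pixels
      o <- order(abs(nb[, 1L] - r) + abs(nb[, 2L] - c))
      r <- nb[o[1L], 1L]; c <- nb[o[1L], 2L]
    }
    path[seq_len(n), , drop = FALSE]
  }

  deg2 <- function(r, c) nrow(neighbors(r, c))
  paths <- list()
  # open paths first: start at endpoints (<= 1 remaining neighbor)
  repeat {
    todo <- alive[!visited[alive]]
    if (length(todo) == 0L) break
    rs <- (todo - 1L) %% nr + 1L
    cs <- (todo - 1L) %/% nr + 1L
    d <- mapply(deg2, rs, cs)
    start <- if (any(d <= 1L)) which(d <= 1L)[1L] else 1L  # else: closed loop
    paths[[length(paths) + 1L]] <- walk_from(rs[start], cs[start])
  }

  # split at sharp chord-angle changes
  split_sharp <- function(p) {
    n <- nrow(p)
    if (n < 11L) return(list(p))
    ang <- rep(0, n)
    for (i in 6:(n - 5L)) {
      v1 <- p[i, ] - p[i - 5L, ]
      v2 <- p[i + 5L, ] - p[i, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang[i] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }
    brk <- integer(0)
    i <- 6L
    while (i <= n - 5L) {
      if (ang[i] > breakpoint_angle_deg) {
        # local maximum of the exceedance run
        j <- i
        while (j < n - 5L && ang[j + 1L] > breakpoint_angle_deg) j <- j + 1L
        brk <- c(brk, (i:j)[which.max(ang[i:j])])
        i <- j + 1L
      } else i <- i + 1L
    }
    if (length(brk) == 0L) return(list(p))
    starts <- c(1L, brk + 1L)
    ends <- c(brk, n)
    lapply(seq_along(starts), function(k) p[starts[k]:ends[k], , drop = FALSE])
  }
  pieces <- unlist(lapply(paths, split_sharp), recursive = FALSE)

  keep <- vapply(pieces, nrow, integer(1L)) >= min_line_length_px
  short_px <- sum(vapply(pieces[!keep], nrow, integer(1L)))
  structure(pieces[keep],
            junction_pixels = n_junction,
            short_pixels = as.integer(short_px))
}
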
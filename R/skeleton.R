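#' Topology-preserving thinning of a binary mask
#'
#' Reduces every foreground shape to a 1-pixel-wide centerline using
#' Zhang-Suen two-subiteration thinning. The output is a subset of the
#' input foreground, contains no 2x2 all-foreground block, and preserves
#' connected components and holes for shapes larger than a few pixels.
#'
#' @param mask 0/1 integer matrix (e.g. from [otsu_binarize()]).
#' @return 0/1 integer matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  m <- as_mask(mask)
  if (sum(m) == 0L) stop("empty mask")
  # pad with one background ring so neighbor shifts never wrap
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  shift <- function(x, dr, dc) {
    out <- matrix(0L, nrow(x), ncol(x))
    rs <- seq_len(nrow(x)) - dr
    cs <- seq_len(ncol(x)) - dc
    ok_r <- rs >= 1L & rs <= nrow(x)
    ok_c <- cs >= 1L & cs <= ncol(x)
    out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors p2..p9 clockwise from north (row-1)
      n2 <- shift(p, -1L, 0L); n3 <- shift(p, -1L, 1L); n4 <- shift(p, 0L, 1L)
      n5 <- shift(p, 1L, 1L);  n6 <- shift(p, 1L, 0L);  n7 <- shift(p, 1L, -1L)
      n8 <- shift(p, 0L, -1L); n9 <- shift(p, -1L, -1L)
      b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      a <- (n2 == 0L & n3 == 1L) + (n3 == 0L & n4 == 1L) +
           (n4 == 0L & n5 == 1L) + (n5 == 0L & n6 == 1L) +
           (n6 == 0L & n7 == 1L) + (n7 == 0L & n8 == 1L) +
           (n8 == 0L & n9 == 1L) + (n9 == 0L & n2 == 1L)
      if (sub == 1L) {
        c1 <- n2 * n4 * n6 == 0L
        c2 <- n4 * n6 * n8 == 0L
      } else {
        c1 <- n2 * n4 * n8 == 0L
        c2 <- n2 * n6 * n8 == 0L
      }
      del <- p == 1L & b >= 2L & b <= 6L & a == 1L & c1 & c2
      if (any(del)) {
        p[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- p[2:(nr + 1L), 2:(nc + 1L)]
  structure(out, class = c("binary_mask", class(out)))
}
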
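#' Skeletonize a binary mask by morphological thinning
#'
#' Zhang-Suen thinning: iteratively peels boundary pixels in two alternating
#' subiterations until the foreground is a one-pixel-wide, 8-connected
#' skeleton. Used to reduce segmented strokes to curves before radius
#' sampling.
#'
#' @param mask logical matrix, or grayscale matrix where foreground is
#'   \code{> 0}.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  p <- if (is.logical(mask)) mask else mask > 0
  if (!any(p)) return(p)
  nr <- nrow(p); nc <- ncol(p)
  # pad with background so neighbor shifts never wrap
  z <- matrix(FALSE, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- p
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- (1L + max(dr, 0L)):(nrow(m) + min(dr, 0L))
    cs <- (1L + max(dc, 0L)):(ncol(m) + min(dc, 0L))
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors clockwise from north: P2..P9
      n2 <- shift(z, 1L, 0L);  n3 <- shift(z, 1L, -1L)
      n4 <- shift(z, 0L, -1L); n5 <- shift(z, -1L, -1L)
      n6 <- shift(z, -1L, 0L); n7 <- shift(z, -1L, 1L)
      n8 <- shift(z, 0L, 1L);  n9 <- shift(z, 1L, 1L)
      b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      a <- (!n2 & n3) + (!n3 & n4) + (!n4 & n5) + (!n5 & n6) +
           (!n6 & n7) + (!n7 & n8) + (!n8 & n9) + (!n9 & n2)
      if (sub == 1L) {
        cond <- !(n2 & n4 & n6) & !(n4 & n6 & n8)
      } else {
        cond <- !(n2 & n4 & n8) & !(n2 & n6 & n8)
      }
      del <- z & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        z[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  z[2:(nr + 1L), 2:(nc + 1L)]
}
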
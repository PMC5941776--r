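#' Quantize a grayscale image into co-occurrence levels
#'
#' Uniform-width binning of \code{[0, 255]} into \code{n_levels} levels:
#' \code{level = floor(intensity * n_levels / 256)}, spanning
#' \code{0..n_levels-1}.
#'
#' @param img grayscale matrix, intensities in \code{[0, 255]}.
#' @param n_levels number of levels, in \code{[2, 256]}.
#' @return integer matrix of levels.
#' @export
quantize <- function(img, n_levels = 8L) {
  if (!is_count(n_levels, 2L) || n_levels > 256)
    stopf("n_levels must be an integer in [2, 256]", class = "scmhand_bad_param")
  nl <- as.integer(n_levels)
  lv <- floor(img * nl / 256)
  storage.mode(lv) <- "integer"
  pmin(pmax(lv, 0L), nl - 1L)
}

#' Structural co-occurrence matrix of two pixel-aligned images
#'
#' Builds the two-image structural co-occurrence matrix (SCM): a normalized
#' joint histogram of the quantized intensities of \code{f} and \code{g}
#' paired at identical pixel positions. Entry \eqn{m_{ij}} is the fraction of
#' positions where \code{f} falls in level \eqn{i} and \code{g} in level
#' \eqn{j}. In the classical formulation the second signal is a filtered
#' version of the first; here it is a second image, so the matrix captures
#' the structural similarity of the pair — e.g. a patient's pen trace against
#' the exam template it was meant to follow.
#'
#' @param f,g grayscale matrices with identical dimensions, intensities 0-255.
#' @param n_levels quantization levels (default 8).
#' @return an object of class \code{"scm"}: list with \code{m} (the
#'   \code{n_levels x n_levels} probability matrix), \code{n_levels},
#'   \code{p_row} (row marginal \eqn{P^r}: sums over columns per row) and
#'   \code{p_col} (column marginal \eqn{P^c}: sums over rows per column).
#' @examples
#' f <- matrix(c(0, 0, 255, 255), 2, 2, byrow = TRUE)
#' g <- matrix(c(0, 255, 0, 255), 2, 2, byrow = TRUE)
#' scm(f, g, n_levels = 2)
#' @export
scm <- function(f, g, n_levels = 8L) {
  if (!identical(dim(f), dim(g)))
    stopf("images must have identical dimensions", class = "scmhand_dim_mismatch")
  lf <- quantize(f, n_levels)
  lg <- quantize(g, n_levels)
  counts <- tabulate(lf + n_levels * lg + 1L, nbins = n_levels * n_levels)
  m <- matrix(counts, n_levels, n_levels) / length(lf)
  new_scm(m)
}

# Wrap an already-normalized matrix as an scm object (also the entry point
# for tests that construct matrices directly).
new_scm <- function(m) {
  structure(list(m = m, n_levels = nrow(m),
                 p_row = rowSums(m), p_col = colSums(m)),
            class = "scm")
}

#' @export
print.scm <- function(x, ...) {
  cat(sprintf("Structural co-occurrence matrix (%d levels)\n", x$n_levels))
  cat(sprintf("  diagonal mass %.3f, off-diagonal mass %.3f\n",
              sum(diag(x$m)), 1 - sum(diag(x$m))))
  invisible(x)
}

# Accept either an scm object or a plain normalized matrix.
scm_mat <- function(x) {
  if (inherits(x, "scm")) x$m
  else if (is.matrix(x)) x
  else stopf("expected an 'scm' object or matrix", class = "scmhand_bad_param")
}

#' Quadrant marginal distributions of an SCM
#'
#' Quadrant I is the top-left \code{N/2 x N/2} block (low levels in both
#' images) and quadrant III the bottom-right block (high levels in both);
#' each is summarised as its within-quadrant row-sum vector.
#'
#' @param x an \code{scm} object or normalized matrix with an even number of
#'   levels.
#' @return list with \code{p1} and \code{p3}, each of length \code{N/2}.
#' @export
quadrant_distributions <- function(x) {
  m <- scm_mat(x)
  n <- nrow(m)
  if (n %% 2L != 0L)
    stopf("quadrant distributions require an even number of levels",
          class = "scmhand_bad_param")
  h <- n %/% 2L
  lo <- seq_len(h); hi <- (h + 1L):n
  list(p1 = rowSums(m[lo, lo, drop = FALSE]),
       p3 = rowSums(m[hi, hi, drop = FALSE]))
}
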
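#' Scalar attributes of a structural co-occurrence matrix
#'
#' Eight attributes summarise the SCM \eqn{M = (m_{ij})} in three groups.
#' Statistical group: correlation (COR), inverse difference moment (IDM) and
#' entropy (ENT) read the joint mass directly. Information group: chi-square
#' distance (CSD) between the observed diagonal and the row marginal, and the
#' chi-square distance ratio (CSR) between the quadrant-I distribution and
#' the quadrant-I/III average. Divergent group: the mean absolute difference
#' ratio (MDR) of the two marginals' index dispersions, the Kullback-Leibler
#' divergence (DKL) of the column marginal from the row marginal, and the
#' complementary absolute difference (CAD). Logarithms are base 2
#' (attributes in bits).
#'
#' Zero-mass guards follow the definitions: chi-square terms with a zero
#' denominator are dropped; DKL terms are zero wherever either marginal
#' vanishes; MDR is 1 when both dispersions are 0 (identical degenerate
#' marginals); COR is \code{NA} when either marginal has zero index variance
#' (e.g. a constant image), to be imputed downstream.
#'
#' @param x an \code{scm} object (see [scm()]) or a normalized
#'   \code{N x N} matrix.
#' @return each attribute function returns a single numeric;
#'   \code{scm_features()} returns a named vector in the fixed order
#'   \code{cor, idm, ent, csd, csr, mdr, dkl, cad}.
#' @name scm_features
NULL

#' @rdname scm_features
#' @export
scm_cor <- function(x) {
  m <- scm_mat(x)
  idx <- seq_len(nrow(m)) - 1
  pr <- rowSums(m); pc <- colSums(m)
  mu_i <- sum(idx * pr); mu_j <- sum(idx * pc)
  var_i <- sum((idx - mu_i)^2 * pr); var_j <- sum((idx - mu_j)^2 * pc)
  if (var_i <= 0 || var_j <= 0) return(NA_real_)
  sum(m * outer(idx - mu_i, idx - mu_j)) / sqrt(var_i * var_j)
}

#' @rdname scm_features
#' @export
scm_idm <- function(x) {
  m <- scm_mat(x)
  idx <- seq_len(nrow(m)) - 1
  sum(m / (1 + abs(outer(idx, idx, "-"))))
}

#' @rdname scm_features
#' @export
scm_ent <- function(x) {
  m <- scm_mat(x)
  p <- m[m > 0]
  -sum(p * log2(p))
}

#' @rdname scm_features
#' @export
scm_csd <- function(x) {
  m <- scm_mat(x)
  p0 <- diag(m)
  pe <- rowSums(m)
  ok <- pe > 0
  sum((p0[ok] - pe[ok])^2 / pe[ok])
}

#' @rdname scm_features
#' @export
scm_csr <- function(x) {
  q <- quadrant_distributions(x)
  pm <- (q$p1 + q$p3) / 2
  ok <- pm > 0
  sum((q$p1[ok] - pm[ok])^2 / pm[ok])
}

# index dispersion of a marginal: sum over its nonzero support of
# P(S_i) P(S_j) |S_i - S_j|
mean_abs_dispersion <- function(p) {
  s <- which(p > 0) - 1
  ps <- p[p > 0]
  sum(outer(ps, ps) * abs(outer(s, s, "-")))
}

#' @rdname scm_features
#' @export
scm_mdr <- function(x) {
  o <- if (inherits(x, "scm")) x else new_scm(scm_mat(x))
  md_c <- mean_abs_dispersion(o$p_col)
  md_r <- mean_abs_dispersion(o$p_row)
  if (md_c == 0 && md_r == 0) return(1)
  min(md_c, md_r) / max(md_c, md_r)
}

#' @rdname scm_features
#' @export
scm_dkl <- function(x) {
  o <- if (inherits(x, "scm")) x else new_scm(scm_mat(x))
  pc <- o$p_col; pr <- o$p_row
  ok <- pc > 0 & pr > 0
  sum(pc[ok] * log2(pc[ok] / pr[ok]))
}

#' @rdname scm_features
#' @export
scm_cad <- function(x) {
  o <- if (inherits(x, "scm")) x else new_scm(scm_mat(x))
  1 - sum(abs(o$p_col - o$p_row))
}

#' @rdname scm_features
#' @export
scm_features <- function(x) {
  o <- if (inherits(x, "scm")) x else new_scm(scm_mat(x))
  c(cor = scm_cor(o), idm = scm_idm(o), ent = scm_ent(o),
    csd = scm_csd(o), csr = scm_csr(o), mdr = scm_mdr(o),
    dkl = scm_dkl(o), cad = scm_cad(o))
}
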
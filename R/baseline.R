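#' Angular radius profile of a curve mask
#'
#' Thins the mask foreground to a skeleton, then samples the curve's radius
#' about a center point in \code{n} equal angular bins. Within a bin the
#' skeleton pixels of a multi-winding curve form radially separated strands
#' (one per winding); \eqn{r^i} is the unweighted mean of the strand means,
#' so every winding contributes equally regardless of how many pixels its
#' arc leaves in the bin. For an exam pair the center is taken from the
#' template skeleton's centroid and shared with the trace so both profiles
#' use one origin. Empty bins are filled by linear interpolation from their
#' angular neighbors (circularly).
#'
#' The default of 72 bins (5 degrees) keeps every bin wider than the largest
#' angular gap between consecutive skeleton pixels on the innermost winding
#' of a 256-px exam, so no bin silently loses a winding.
#'
#' @param mask logical or 0/255 grayscale matrix of the curve.
#' @param n number of angular bins (default 72).
#' @param center optional \code{c(row, col)} center; defaults to the
#'   skeleton centroid.
#' @param strand_gap_px radial gap splitting a bin's pixels into strands;
#'   must be below the curve's winding spacing.
#' @return an object of class \code{"radius_profile"}: list with
#'   \code{radii} (length \code{n}), \code{center}, \code{n}.
#' @export
radius_profile <- function(mask, n = 72L, center = NULL, strand_gap_px = 10) {
  if (!is_count(n, 2L))
    stopf("n must be an integer >= 2", class = "scmhand_bad_param")
  sk <- skeletonize(mask)
  pix <- which(sk, arr.ind = TRUE)
  if (nrow(pix) < 2L)
    stopf("mask skeleton has fewer than 2 pixels", class = "scmhand_degenerate")
  if (is.null(center)) center <- colMeans(pix)
  dy <- pix[, 1] - center[1]
  dx <- pix[, 2] - center[2]
  ang <- atan2(dy, dx) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi) * n) + 1L, n)
  r <- sqrt(dx^2 + dy^2)
  radii <- as.numeric(tapply(r, factor(bin, levels = seq_len(n)),
                             strand_mean, gap = strand_gap_px))
  filled <- !is.na(radii)
  if (sum(filled) < 2L)
    stopf("fewer than 2 nonempty angular bins", class = "scmhand_degenerate")
  if (any(!filled)) radii <- interp_circular(radii)
  structure(list(radii = radii, center = as.numeric(center), n = as.integer(n)),
            class = "radius_profile")
}

# mean of per-strand means: sorted radii split where consecutive values
# jump by more than `gap` (i.e. at winding boundaries)
strand_mean <- function(r, gap) {
  r <- sort(r)
  grp <- cumsum(c(0, diff(r) > gap))
  mean(tapply(r, grp, mean))
}

# linear interpolation over gaps in a circular sequence: replicate the
# filled samples one period to each side, then interpolate the gaps
interp_circular <- function(x) {
  n <- length(x)
  f <- which(!is.na(x))
  miss <- which(is.na(x))
  x[miss] <- stats::approx(c(f - n, f, f + n), rep(x[f], 3), xout = miss)$y
  x
}

#' Radius-difference attributes of a trace/template profile pair
#'
#' The nine classical attributes comparing a handwritten-trace (HT) radius
#' profile to its exam-template (ET) profile: root mean square of the radial
#' difference, its extreme values and standard deviation, the mean relative
#' tremor (MRT: mean absolute difference between radius samples separated by
#' a displacement \code{d}), the ET radius extremes, the sd of the HT radii,
#' and the number of sign changes of the difference sequence (zeros carry no
#' sign and are skipped).
#'
#' @param r_ht,r_et \code{\link{radius_profile}} objects (or numeric vectors)
#'   of equal length.
#' @param d sample-point displacement used by MRT, \code{1 <= d < n}.
#' @param mrt_on profile MRT is computed on: \code{"ht"} (a trace carries the
#'   tremor; default) or \code{"et"} (verbatim template mode).
#' @return named list of class \code{"baseline_features"} with elements
#'   \code{rms, delta_max, delta_min, sd_diff, mrt, max_et_radius,
#'   min_et_radius, sd_ht_radius, sign_changes}.
#' @export
baseline_features <- function(r_ht, r_et, d = 10L, mrt_on = c("ht", "et")) {
  mrt_on <- match.arg(mrt_on)
  ht <- if (inherits(r_ht, "radius_profile")) r_ht$radii else as.numeric(r_ht)
  et <- if (inherits(r_et, "radius_profile")) r_et$radii else as.numeric(r_et)
  n <- length(ht)
  if (length(et) != n)
    stopf("profiles must have equal length", class = "scmhand_dim_mismatch")
  if (!is_count(d, 1L) || d >= n)
    stopf("d must satisfy 1 <= d < n", class = "scmhand_bad_param")
  dif <- ht - et
  sgn <- sign(dif)[sign(dif) != 0]
  out <- list(
    rms = sqrt(mean(dif^2)),
    delta_max = max(dif),
    delta_min = min(dif),
    sd_diff = stats::sd(dif),
    mrt = mrt(if (mrt_on == "ht") ht else et, d),
    max_et_radius = max(et),
    min_et_radius = min(et),
    sd_ht_radius = stats::sd(ht),
    sign_changes = if (length(sgn) < 2L) 0L else sum(diff(sgn) != 0)
  )
  structure(out, class = "baseline_features")
}

# mean absolute difference between samples r^i and r^{i-d+1}
# (0-based i = d .. n-1), i.e. an effective lag of d-1
mrt <- function(r, d) {
  n <- length(r)
  i <- (d + 1L):n
  mean(abs(r[i] - r[i - d + 1L]))
}

#' @export
print.baseline_features <- function(x, ...) {
  v <- unlist(x)
  cat("Radius-difference attributes:\n")
  print(round(v, 4))
  invisible(x)
}
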
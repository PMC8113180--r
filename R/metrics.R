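## Volumetric image-similarity metrics, computed over masked voxel vectors:
## mean squared error, a single global SSIM statistic, the signed mean
## relative error (MRE, %) with its mean-of-absolute-values cohort summary,
## and histogram intersection. Plus region-wise reporting over the standard
## ROIs (whole brain, cortical GM, eroded WM, reference region).

#' Mean squared error of two masked voxel vectors
#' @param x,y numeric vectors of equal length (estimate, ground truth).
#' @return Scalar \eqn{(1/n) \sum_i (x_i - y_i)^2}.
#' @export
mse <- function(x, y) {
  if (length(x) != length(y)) stop("vector length mismatch", call. = FALSE)
  if (length(x) < 1) stop("empty vectors", call. = FALSE)
  mean((x - y)^2)
}

#' Global structural similarity of two masked voxel vectors
#'
#' The single-statistic SSIM over the whole masked region (no sliding
#' window): `(2*mx*my + c1)(2*cov + c2) / ((mx^2 + my^2 + c1)(vx + vy + c2))`
#' with `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`. Moments use the population
#' (1/n) convention. `L` is the dynamic range; by default the range of the
#' pooled values.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param L dynamic range; default `max(c(x, y)) - min(c(x, y))`.
#' @return Scalar in \[-1, 1\]; exactly 1 for identical inputs.
#' @export
ssim <- function(x, y, L = NULL) {
  if (length(x) != length(y)) stop("vector length mismatch", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 voxels", call. = FALSE)
  if (is.null(L)) L <- max(c(x, y)) - min(c(x, y))
  if (L <= 0) {
    if (identical(x, y)) return(1)
    stop("dynamic range L must be positive", call. = FALSE)
  }
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean(x^2) - mx^2
  vy <- mean(y^2) - my^2
  cxy <- mean(x * y) - mx * my
  ((2 * mx * my + c1) * (2 * cxy + c2)) / ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Signed mean relative error (%)
#'
#' Relative difference between the mean of the ground truth and the mean of
#' the estimate, with respect to the ground-truth mean:
#' `100 * (mean(y) - mean(x)) / mean(y)`. Positive values mean the estimate
#' under-estimates the truth.
#'
#' @param x numeric vector, the estimate.
#' @param y numeric vector, the ground truth; `mean(y)` must be non-zero.
#' @return Scalar signed percentage.
#' @export
mre_pct <- function(x, y) {
  if (length(x) != length(y)) stop("vector length mismatch", call. = FALSE)
  my <- mean(y)
  if (my == 0) stop("ground-truth mean is zero; relative error undefined", call. = FALSE)
  100 * (my - mean(x)) / my
}

#' Cohort summary of per-subject MRE values
#' @param subject_mres numeric vector of signed per-subject MRE percentages.
#' @return Mean of the absolute values.
#' @export
cohort_mre <- function(subject_mres) {
  if (length(subject_mres) < 1) stop("no subject MRE values", call. = FALSE)
  mean(abs(subject_mres))
}

#' Histogram intersection of two masked voxel vectors
#'
#' Histograms are computed over `n_bins` shared equal-width bins spanning
#' the pooled range of both inputs and normalized to sum to one; the
#' intersection is the sum over bins of the element-wise minimum, in
#' \[0, 1\], with 1 for identical distributions. If all values of both
#' inputs are identical (degenerate range) the intersection is 1 by
#' convention.
#'
#' @param x,y numeric vectors.
#' @param n_bins number of bins (>= 2), default 64.
#' @return Scalar in \[0, 1\].
#' @export
histogram_intersection <- function(x, y, n_bins = 64) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  rng <- range(c(x, y))
  if (rng[1] == rng[2]) return(1)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  hx <- findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE)
  hy <- findInterval(y, brk, rightmost.closed = TRUE, all.inside = TRUE)
  cx <- tabulate(hx, n_bins) / length(x)
  cy <- tabulate(hy, n_bins) / length(y)
  sum(pmin(cx, cy))
}

#' Region-wise metric report
#'
#' Computes all four metrics (MSE, SSIM, MRE %, HI) between an estimate and
#' a ground-truth volume inside each region mask: whole brain, cortical GM,
#' WM and reference region. The WM mask is morphologically eroded
#' (6-connectivity, `erode_wm` iterations) before evaluation to avoid
#' contamination from specific GM uptake at the boundary.
#'
#' @param estimate,truth 3D arrays on one grid.
#' @param masks named list of logical arrays `wb`, `gm`, `wm`, `reference`.
#' @param erode_wm erosion iterations applied to the WM mask (default 2).
#' @param n_bins histogram bins for HI.
#' @param L dynamic range for SSIM; default per-region pooled range.
#' @return data.frame with one row per region: region, n_voxels, mse, ssim,
#'   mre_pct, hi.
#' @export
region_report <- function(estimate, truth, masks, erode_wm = 2, n_bins = 64, L = NULL) {
  stopifnot_shape(estimate, truth, "estimate / truth")
  regions <- list(WB = masks$wb, GM = masks$gm,
                  WM = erode3d(masks$wm, erode_wm), reference = masks$reference)
  rows <- lapply(names(regions), function(rn) {
    m <- regions[[rn]]
    if (!any(m)) {
      stop(sprintf("region mask '%s' is empty%s", rn,
                   if (rn == "WM") " after erosion" else ""), call. = FALSE)
    }
    xv <- estimate[m]; yv <- truth[m]
    data.frame(region = rn, n_voxels = sum(m), mse = mse(xv, yv),
               ssim = ssim(xv, yv, L), mre_pct = mre_pct(xv, yv),
               hi = histogram_intersection(xv, yv, n_bins),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
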
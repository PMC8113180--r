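## The two-template amyloid-load model: each SUVr image is fitted as a
## linear combination of an NS-binding template and an amyloid-deposition
## template, both derived from a cross-sectional pool. The deposition
## coefficient is the global amyloid load AbL; the NS coefficient is ns.

#' Derive NS and deposition templates from a cross-sectional pool
#'
#' The NS template is the voxel-wise mean of the low-burden subset of the
#' pool (the lowest-global-SUVr half by default). The deposition template is
#' the first principal axis of the mean-centered pool restricted to
#' `fit_mask`, scaled to unit root-mean-square within the mask and
#' sign-oriented so that its cortical-GM mean is positive.
#'
#' @param pool list of SUVr volumes (3D arrays or `sabl_suvr`) on one grid.
#' @param fit_mask logical 3D array defining the fit support.
#' @param gm_mask optional cortical GM mask used for the sign convention;
#'   defaults to `fit_mask`.
#' @param low_fraction fraction of the pool (lowest global SUVr) averaged
#'   into the NS template.
#' @return An object of class `sabl_templates`: `ns_template`,
#'   `deposition_template` (3D arrays, zero outside `fit_mask`), `fit_mask`.
#' @export
build_templates <- function(pool, fit_mask, gm_mask = NULL, low_fraction = 0.5) {
  stopifnot(length(pool) >= 3)
  vols <- lapply(pool, function(v) if (inherits(v, "sabl_suvr")) v$data else v)
  for (v in vols) stopifnot_shape(v, fit_mask, "pool volume / fit mask")
  if (is.null(gm_mask)) gm_mask <- fit_mask
  nmask <- sum(fit_mask)
  M <- vapply(vols, function(v) v[fit_mask], numeric(nmask))  # nmask x n

  globals <- colMeans(M)
  n_low <- max(1L, floor(length(vols) * low_fraction))
  low_idx <- select_training_set(globals, n_low)
  ns_vec <- rowMeans(M[, low_idx, drop = FALSE])

  Mc <- M - rowMeans(M)
  sv <- svd(Mc, nu = 1, nv = 0)
  if (sv$d[1] < 1e-10 * max(1, max(abs(M)))) {
    stop("degenerate pool: no variance across volumes, cannot derive a deposition template",
         call. = FALSE)
  }
  # scale the principal axis to unit root-mean-square over the mask, so the
  # fitted deposition coefficient is on the same footing as the NS
  # coefficient and insensitive to voxel-level noise
  dep_vec <- sv$u[, 1] * sqrt(nmask)

  dep <- array(0, dim(fit_mask)); dep[fit_mask] <- dep_vec
  if (roi_mean(dep, gm_mask) < 0) dep <- -dep
  ns <- array(0, dim(fit_mask)); ns[fit_mask] <- ns_vec

  # the two templates must span a genuinely two-dimensional model
  u1 <- ns[fit_mask]; u2 <- dep[fit_mask]
  cosang <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
  if (acos(clamp(abs(cosang), 0, 1)) <= 1e-3) {
    stop("deposition template is collinear with the NS template", call. = FALSE)
  }
  structure(list(ns_template = ns, deposition_template = dep, fit_mask = fit_mask),
            class = "sabl_templates")
}

#' Fit the two-template amyloid-load model to an SUVr image
#'
#' Ordinary least squares of the masked SUVr image on the deposition and NS
#' templates (no intercept). The deposition coefficient is the global
#' amyloid load AbL, the NS coefficient quantifies the global NS level.
#'
#' @param suvr an `sabl_suvr` or 3D array on the template grid.
#' @param templates an `sabl_templates` from [build_templates()].
#' @return list with `abl`, `ns_coeff`, `residual_rms`.
#' @export
fit_abl <- function(suvr, templates) {
  data <- if (inherits(suvr, "sabl_suvr")) suvr$data else suvr
  stopifnot_shape(data, templates$fit_mask, "SUVr / template grid")
  m <- templates$fit_mask
  A <- cbind(dep = templates$deposition_template[m], ns = templates$ns_template[m])
  cosang <- abs(sum(A[, 1] * A[, 2])) / sqrt(sum(A[, 1]^2) * sum(A[, 2]^2))
  if (1 - cosang < 1e-12) {
    stop("templates are collinear within the fit mask; the fit is ill-conditioned",
         call. = FALSE)
  }
  fit <- stats::lm.fit(A, data[m])
  co <- fit$coefficients
  list(abl = unname(co["dep"]), ns_coeff = unname(co["ns"]),
       residual_rms = sqrt(mean(fit$residuals^2)))
}
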
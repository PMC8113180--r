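## Synthetic multimodal brain-phantom cohorts.
##
## Each phantom is a co-registered stack of T1-weighted MRI, T2-FLAIR MRI and
## an amyloid-PET SUVr image on one isotropic grid, built from a labelled
## ellipsoidal-shell anatomy (CSF / cortical GM / WM / deep GM plus a separate
## cerebellar compartment serving as the amyloid-free reference region).
## Nonspecific (NS) tracer uptake is WM-dominant with inter-subject global
## variability and local reductions inside cerebrovascular lesions (WMH,
## lacunes, cortical infarcts); specific uptake is a smooth cortical
## deposition pattern scaled by a per-subject amyloid burden. The observed
## PET is point-spread blurred (spill-over), noised and normalized by the
## reference-region mean, so it is in SUVr units.

# Tissue label codes shared across the package.
LBL <- c(bg = 0L, csf = 1L, gm = 2L, wm = 3L, dgm = 4L, cbgm = 5L, cbwm = 6L)

#' Generator settings for the phantom cohort
#'
#' Returns the full set of generator defaults, optionally overridden. Unknown
#' keys are rejected by name. The defaults define the simulated study
#' conditions: a memory-clinic-like cohort enriched in cerebrovascular
#' disease (CeVD), with a 70/30 low/high amyloid-burden mixture, diffuse and
#' lesion-driven NS variability, and MRI contrast coupled to the myelin level
#' that drives NS binding (see the methods vignette for rationale).
#'
#' @param ... named overrides of the defaults.
#' @return A named list of generator settings.
#' @export
#' @examples
#' cfg <- phantom_config(grid = c(32, 32, 32), p_high = 0)
phantom_config <- function(...) {
  cfg <- list(
    grid = c(48L, 48L, 48L),
    voxel_size_mm = c(2, 2, 2),
    # amyloid burden mixture (SUVr units of cortical specific uptake)
    p_high = 0.3,
    burden_low_sd = 0.05,
    burden_high_mean = 0.8,
    burden_high_sd = 0.25,
    burden_high_min = 0.2,
    # global NS variability and diffuse CeVD effect on NS
    gscale_mean = 1.0,
    gscale_sd = 0.06,
    gscale_range = c(0.8, 1.2),
    cevd_ns_slope = 0.15,
    # lesion model
    lesion_rates = c(wmh = 8, lacunes = 3, cortical_infarcts = 1.5, cmbs = 2.5),
    lesion_ns_reduction = 0.5,
    # NS base profile per tissue, SUVr-like units (bg, csf, gm, wm, dgm, cbgm, cbwm)
    ns_base = c(0, 0.12, 0.55, 1.35, 0.70, 0.55, 1.30),
    # PET observation model
    psf_fwhm_mm = 6,
    pet_noise_sd = 0.04,
    # MRI observation model: tissue means and lesion contrast factors
    t1_means = c(0, 0.25, 0.62, 0.85, 0.66, 0.62, 0.85),
    flair_means = c(0, 0.14, 0.55, 0.45, 0.52, 0.55, 0.45),
    wm_t1_coupling = 0.7,
    wm_flair_coupling = -1.2,
    lesion_t1_factor = c(wmh = 0.75, lacunes = 0.45, cortical_infarcts = 0.55, cmbs = 0.55),
    lesion_flair_factor = c(wmh = 1.9, lacunes = 0.5, cortical_infarcts = 0.7, cmbs = 0.55),
    mri_smooth_sigma = 0.6,
    mri_noise_sd = 0.02,
    bias_amplitude = 0.05,
    # covariate model
    cognition_intercept = 28,
    cognition_burden_slope = 5,
    cognition_lesion_slope = 0.25,
    cognition_noise_sd = 1.2,
    atrophy_base = 0.12,
    atrophy_burden_slope = 0.25,
    atrophy_severity_slope = 0.15,
    atrophy_noise_sd = 0.06,
    hippo_base = 4.0,
    hippo_burden_slope = 1.0,
    hippo_noise_sd = 0.3
  )
  override <- list(...)
  if (length(override) == 1L && is.null(names(override)) && is.list(override[[1]])) {
    override <- override[[1]]
  }
  if (length(override)) {
    bad <- setdiff(names(override), names(cfg))
    if (length(bad)) stop("unknown generator setting(s): ", paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(override)] <- override
  }
  cfg
}

#' Generate a labelled phantom anatomy
#'
#' Builds nested, smoothly perturbed ellipsoidal shells for CSF, cortical
#' grey matter and white matter, with central ventricles, two deep-GM
#' nuclei, and a spatially separate cerebellar compartment whose grey matter
#' is the amyloid-free reference region. Higher `atrophy` thins the cortical
#' GM shell monotonically (the lost voxels become CSF), emulating the
#' atrophy-driven aggravation of WM-to-GM spill-over.
#'
#' @param grid_shape integer 3-vector, each entry >= 32.
#' @param atrophy scalar in \[0, 1\]; 0 = none, 1 = maximal cortical thinning.
#' @param seed integer seed for the boundary perturbation field.
#' @param voxel_size_mm voxel size, mm.
#' @return An object of class `sabl_anatomy`: list with `labels` (integer 3D
#'   array using codes 0=background, 1=CSF, 2=cortical GM, 3=WM, 4=deep GM,
#'   5=cerebellar GM (reference), 6=cerebellar WM) and `voxel_size_mm`.
#' @export
generate_anatomy <- function(grid_shape, atrophy, seed, voxel_size_mm = c(2, 2, 2)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 32)) {
    stop("grid too small: each dimension must be >= 32 to contain all compartments", call. = FALSE)
  }
  stopifnot(atrophy >= 0, atrophy <= 1)
  d <- grid_shape
  ax_coords <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))

  rho <- function(center_frac, axes_frac, pert = NULL) {
    ctr <- center_frac * d
    axs <- axes_frac * d
    x2 <- ((ax_coords[[1]] - ctr[1]) / axs[1])^2
    y2 <- ((ax_coords[[2]] - ctr[2]) / axs[2])^2
    z2 <- ((ax_coords[[3]] - ctr[3]) / axs[3])^2
    r <- sqrt(outer(outer(x2, y2, `+`), z2, `+`))
    if (!is.null(pert)) r <- r + pert
    r
  }

  pert <- smooth_field3d(d, scale = max(6, round(min(d) / 6)), amplitude = 0.035, seed = seed)

  labels <- array(LBL["bg"], d)

  # cerebrum: CSF rind, cortical GM shell, WM core
  r_c <- rho(c(0.50, 0.52, 0.64), c(0.40, 0.44, 0.26), pert)
  g_out <- 0.90 - 0.08 * atrophy
  w_out <- 0.70
  labels[r_c <= 1] <- LBL["csf"]
  labels[r_c <= g_out] <- LBL["gm"]
  labels[r_c <= w_out] <- LBL["wm"]

  # lateral ventricles (CSF) carved out of the WM core
  r_v <- rho(c(0.50, 0.52, 0.62), c(0.085, 0.16, 0.08), pert)
  labels[r_v <= 1 & labels == LBL["wm"]] <- LBL["csf"]

  # deep grey nuclei, one per hemisphere, only where WM remains
  for (sgn in c(-1, 1)) {
    r_d <- rho(c(0.50 + sgn * 0.14, 0.54, 0.60), c(0.075, 0.09, 0.075), pert)
    labels[r_d <= 1 & labels == LBL["wm"]] <- LBL["dgm"]
  }

  # cerebellum: separate compartment, inferior-posterior; its GM shell is the
  # reference region and never touches cortical GM
  r_cb <- rho(c(0.50, 0.30, 0.20), c(0.21, 0.17, 0.125), pert)
  cb <- r_cb <= 1 & labels == LBL["bg"]
  labels[cb & r_cb > 0.60] <- LBL["cbgm"]
  labels[cb & r_cb <= 0.60] <- LBL["cbwm"]

  structure(list(labels = labels, voxel_size_mm = voxel_size_mm),
            class = "sabl_anatomy")
}

empty_lesion_set <- function() {
  structure(list(
    wmh = list(centers = matrix(numeric(0), 0, 3), radii = numeric(0)),
    lacunes = list(centers = matrix(numeric(0), 0, 3), radii = numeric(0)),
    cortical_infarcts = list(centers = matrix(numeric(0), 0, 3), radii = numeric(0)),
    cmbs = list(centers = matrix(numeric(0), 0, 3), radii = numeric(0)),
    counts = c(wmh = 0L, lacunes = 0L, cortical_infarcts = 0L, cmbs = 0L),
    wmh_volume_ml = 0
  ), class = "sabl_lesions")
}

#' Inject cerebrovascular-disease lesions
#'
#' Samples spherical lesions of the four CeVD classes (WM hyperintensities,
#' lacunes, cortical infarcts, cerebral microbleeds) with class-specific
#' tissue placement. Lesion counts per class are Poisson with mean
#' proportional to `severity`; `severity = 0` yields an empty lesion set.
#'
#' @param anatomy an `sabl_anatomy`.
#' @param severity scalar in \[0, 1\].
#' @param seed integer seed.
#' @param config a [phantom_config()] list (for the class rate constants).
#' @return An object of class `sabl_lesions`: per-class centers (voxel
#'   coordinates) and radii (voxels), a `counts` summary, and the total WMH
#'   volume in mL.
#' @export
inject_cevd <- function(anatomy, severity, seed, config = phantom_config()) {
  stopifnot(severity >= 0, severity <= 1)
  les <- empty_lesion_set()
  if (severity == 0) return(les)
  lab <- anatomy$labels
  d <- dim(lab)
  eligible <- list(
    wmh = which(lab == LBL["wm"]),
    lacunes = which(lab == LBL["wm"] | lab == LBL["dgm"]),
    cortical_infarcts = which(lab == LBL["gm"]),
    cmbs = which(lab == LBL["gm"] | lab == LBL["wm"] | lab == LBL["dgm"])
  )
  radius_range <- list(wmh = c(1.2, 3), lacunes = c(1, 2),
                       cortical_infarcts = c(1.5, 3.5), cmbs = c(0.5, 1))
  withr::with_seed(seed, {
    for (cls in names(eligible)) {
      n <- stats::rpois(1, config$lesion_rates[[cls]] * severity)
      if (n == 0) next
      idx <- sample(eligible[[cls]], n, replace = TRUE)
      ctr <- t(vapply(idx, function(i) as.double(arrayInd(i, d)), numeric(3)))
      rad <- stats::runif(n, radius_range[[cls]][1], radius_range[[cls]][2])
      les[[cls]] <- list(centers = ctr, radii = rad)
      les$counts[[cls]] <- as.integer(n)
    }
  })
  # WMH volume: voxels of WM covered by any WMH sphere
  if (les$counts[["wmh"]] > 0) {
    cov <- unique(unlist(lapply(seq_len(les$counts[["wmh"]]), function(k) {
      ii <- sphere_indices(d, les$wmh$centers[k, ], les$wmh$radii[k])
      ii[lab[ii] == LBL["wm"]]
    })))
    les$wmh_volume_ml <- length(cov) * prod(anatomy$voxel_size_mm) / 1000
  }
  les
}

total_lesion_count <- function(lesions) sum(lesions$counts)

#' Render the ground-truth uptake maps and covariates
#'
#' The true NS map is the WM-dominant tissue profile, with the supratentorial
#' parenchyma (cortical GM, WM, deep GM) multiplied by `global_ns_scale` --
#' the cerebellar reference keeps unit scale, which is what lets global NS
#' variability survive SUVr normalization -- and with a multiplicative
#' reduction (default 0.5) inside WMH, lacune and infarct spheres.
#' Microbleeds do not alter NS. The true specific map is `burden` times a
#' smooth positive cortical deposition pattern (mean 1 over cortical GM),
#' zero outside cortical GM and hence zero in the reference region.
#' Covariates (cognition, atrophy grade, hippocampal volume) are linear in
#' burden and lesion load plus Gaussian noise.
#'
#' @param anatomy an `sabl_anatomy`.
#' @param lesions an `sabl_lesions`.
#' @param burden nonnegative scalar amyloid burden (SUVr units).
#' @param global_ns_scale positive scalar NS scale.
#' @param deposition_pattern_seed integer seed for the deposition pattern and
#'   covariate noise.
#' @param config a [phantom_config()] list.
#' @param atrophy optional atrophy grade already used for the anatomy; when
#'   supplied it is recorded as the `atrophy_grade` covariate.
#' @return An object of class `sabl_truth`: `ns_true`, `specific_true`,
#'   `burden`, `global_ns_scale`, `lesions`, `covariates`.
#' @export
render_truth <- function(anatomy, lesions, burden, global_ns_scale,
                         deposition_pattern_seed, config = phantom_config(),
                         atrophy = NULL) {
  stopifnot(burden >= 0, global_ns_scale > 0)
  lab <- anatomy$labels
  d <- dim(lab)

  ns <- array(config$ns_base[lab + 1L], d)
  cerebral <- lab == LBL["gm"] | lab == LBL["wm"] | lab == LBL["dgm"]
  ns[cerebral] <- ns[cerebral] * global_ns_scale
  for (cls in c("wmh", "lacunes", "cortical_infarcts")) {
    n <- lesions$counts[[cls]]
    if (n == 0) next
    for (k in seq_len(n)) {
      ii <- sphere_indices(d, lesions[[cls]]$centers[k, ], lesions[[cls]]$radii[k])
      ns[ii] <- ns[ii] * (1 - config$lesion_ns_reduction)
    }
  }

  pat <- exp(smooth_field3d(d, scale = max(8, round(min(d) / 4)), amplitude = 0.5,
                            seed = derive_seed(deposition_pattern_seed, 1L, 11L)))
  gm <- lab == LBL["gm"]
  pat <- pat / mean(pat[gm])
  specific <- array(0, d)
  specific[gm] <- burden * pat[gm]

  nles <- total_lesion_count(lesions)
  cov <- withr::with_seed(derive_seed(deposition_pattern_seed, 2L, 13L), {
    atr <- if (!is.null(atrophy)) atrophy else
      clamp(config$atrophy_base + config$atrophy_burden_slope * burden +
              stats::rnorm(1, 0, config$atrophy_noise_sd), 0, 1)
    list(
      cognition = config$cognition_intercept -
        config$cognition_burden_slope * burden -
        config$cognition_lesion_slope * nles +
        stats::rnorm(1, 0, config$cognition_noise_sd),
      atrophy_grade = atr,
      hippocampal_volume = config$hippo_base -
        config$hippo_burden_slope * burden +
        stats::rnorm(1, 0, config$hippo_noise_sd)
    )
  })

  structure(list(ns_true = ns, specific_true = specific, burden = burden,
                 global_ns_scale = global_ns_scale, lesions = lesions,
                 covariates = cov),
            class = "sabl_truth")
}

#' Render the observed multimodal volumes of one subject
#'
#' PET: Gaussian point-spread blur of (NS + specific), additive Gaussian
#' noise, then division by the reference-region mean of the blurred noisy
#' image, giving SUVr units (reference mean exactly 1). MRI: tissue-mean
#' images with cerebral-WM intensity coupled to the subject's NS scale
#' (myelin drives both), lesion-specific contrast (WMH: T1-dark/FLAIR-bright;
#' lacunes and infarcts: dark in both; microbleeds: small dark foci), light
#' resolution smoothing, a smooth multiplicative bias field and Gaussian
#' noise. Masks are derived from the anatomy labels.
#'
#' The NS component of the observed SUVr image (the blurred true NS map
#' divided by the same reference mean) is attached as attribute `ns_suvr`;
#' it is the ground truth against which NS estimates are evaluated.
#'
#' @param anatomy an `sabl_anatomy`.
#' @param truth an `sabl_truth`.
#' @param psf_fwhm_mm PET point-spread FWHM in mm (>= 0).
#' @param noise_sd PET additive noise SD, pre-normalization units (>= 0).
#' @param seed integer seed for noise and bias fields.
#' @param config a [phantom_config()] list.
#' @return An object of class `sabl_subject`: `t1`, `flair`, `pet` (SUVr),
#'   `masks` (list `wb`, `gm`, `wm`, `reference` of logical arrays),
#'   `voxel_size_mm`; attribute `ns_suvr`.
#' @export
render_observed <- function(anatomy, truth, psf_fwhm_mm = 6, noise_sd = 0.04,
                            seed = 1L, config = phantom_config()) {
  stopifnot(psf_fwhm_mm >= 0, noise_sd >= 0)
  lab <- anatomy$labels
  d <- dim(lab)
  sigma_vox <- psf_fwhm_mm / 2.35482 / anatomy$voxel_size_mm

  blurred <- gaussian_blur3d(truth$ns_true + truth$specific_true, sigma_vox)
  y <- withr::with_seed(derive_seed(seed, 1L, 21L), {
    if (noise_sd > 0) blurred + array(stats::rnorm(prod(d), 0, noise_sd), d) else blurred
  })
  ref <- lab == LBL["cbgm"]
  r <- mean(y[ref])
  if (!is.finite(r) || r <= 0) stop("non-positive reference mean in phantom PET", call. = FALSE)
  pet <- y / r
  ns_suvr <- gaussian_blur3d(truth$ns_true, sigma_vox) / r

  s <- truth$global_ns_scale
  t1m <- config$t1_means
  flm <- config$flair_means
  t1 <- array(t1m[lab + 1L], d)
  fl <- array(flm[lab + 1L], d)
  wm <- lab == LBL["wm"]
  t1[wm] <- t1[wm] * (1 + config$wm_t1_coupling * (s - 1))
  fl[wm] <- fl[wm] * (1 + config$wm_flair_coupling * (s - 1))
  for (cls in c("wmh", "lacunes", "cortical_infarcts", "cmbs")) {
    n <- truth$lesions$counts[[cls]]
    if (n == 0) next
    for (k in seq_len(n)) {
      ii <- sphere_indices(d, truth$lesions[[cls]]$centers[k, ], truth$lesions[[cls]]$radii[k])
      t1[ii] <- t1[ii] * config$lesion_t1_factor[[cls]]
      fl[ii] <- fl[ii] * config$lesion_flair_factor[[cls]]
    }
  }
  t1 <- gaussian_blur3d(t1, rep(config$mri_smooth_sigma, 3))
  fl <- gaussian_blur3d(fl, rep(config$mri_smooth_sigma, 3))
  t1 <- withr::with_seed(derive_seed(seed, 2L, 22L), {
    bias <- 1 + config$bias_amplitude * smooth_field3d(d, scale = max(12, min(d) / 3))
    t1 * bias + array(stats::rnorm(prod(d), 0, config$mri_noise_sd), d)
  })
  fl <- withr::with_seed(derive_seed(seed, 3L, 23L), {
    bias <- 1 + config$bias_amplitude * smooth_field3d(d, scale = max(12, min(d) / 3))
    fl * bias + array(stats::rnorm(prod(d), 0, config$mri_noise_sd), d)
  })

  vols <- structure(list(
    t1 = t1, flair = fl, pet = pet,
    masks = list(wb = lab > 0, gm = lab == LBL["gm"], wm = wm, reference = ref),
    voxel_size_mm = anatomy$voxel_size_mm
  ), class = "sabl_subject")
  attr(vols, "ns_suvr") <- ns_suvr
  vols
}

#' Generate a synthetic phantom cohort
#'
#' Draws per-subject amyloid burden from a two-component low/high mixture,
#' CeVD severity, global NS scale (reduced by a diffuse CeVD effect) and
#' atrophy, then renders anatomy, lesions, ground truth and observed volumes
#' for each subject. Fully deterministic given `(config, seed)`.
#'
#' @param n number of subjects (>= 2).
#' @param config a [phantom_config()] list.
#' @param seed integer master seed; all per-subject streams derive from it.
#' @return An object of class `sabl_cohort`: list with `subjects` (each a
#'   list `volumes` = `sabl_subject`, `truth` = `sabl_truth` carrying
#'   `ns_suvr`, `severity`), plus `config` and `seed`.
#' @export
generate_cohort <- function(n, config = phantom_config(), seed = 1L) {
  if (n < 2) stop("cohort size must be at least 2", call. = FALSE)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    draws <- withr::with_seed(si, {
      high <- stats::runif(1) < config$p_high
      burden <- if (high) {
        max(config$burden_high_min, stats::rnorm(1, config$burden_high_mean, config$burden_high_sd))
      } else {
        abs(stats::rnorm(1, 0, config$burden_low_sd))
      }
      severity <- stats::runif(1)
      g0 <- clamp(stats::rnorm(1, config$gscale_mean, config$gscale_sd),
                  config$gscale_range[1], config$gscale_range[2])
      gscale <- max(0.4, g0 - config$cevd_ns_slope * severity)
      atrophy <- clamp(config$atrophy_base + config$atrophy_burden_slope * burden +
                         config$atrophy_severity_slope * severity +
                         stats::rnorm(1, 0, config$atrophy_noise_sd), 0, 1)
      list(burden = burden, severity = severity, gscale = gscale, atrophy = atrophy)
    })
    anatomy <- generate_anatomy(config$grid, draws$atrophy, derive_seed(si, 1L, 31L),
                                voxel_size_mm = config$voxel_size_mm)
    lesions <- inject_cevd(anatomy, draws$severity, derive_seed(si, 2L, 32L), config)
    truth <- render_truth(anatomy, lesions, draws$burden, draws$gscale,
                          derive_seed(si, 3L, 33L), config, atrophy = draws$atrophy)
    vols <- render_observed(anatomy, truth, config$psf_fwhm_mm, config$pet_noise_sd,
                            derive_seed(si, 4L, 34L), config)
    truth$ns_suvr <- attr(vols, "ns_suvr")
    truth$severity <- draws$severity
    attr(vols, "ns_suvr") <- NULL
    subjects[[i]] <- list(volumes = vols, truth = truth)
  }
  structure(list(subjects = subjects, config = config, seed = seed),
            class = "sabl_cohort")
}

#' Per-subject summary table of a phantom cohort
#'
#' @param cohort an `sabl_cohort`.
#' @return data.frame with subject id, true burden, severity, NS scale,
#'   lesion counts, WMH volume and covariates.
#' @export
cohort_table <- function(cohort) {
  rows <- lapply(seq_along(cohort$subjects), function(i) {
    tr <- cohort$subjects[[i]]$truth
    data.frame(
      subject_id = sprintf("sub-%03d", i),
      burden = tr$burden,
      severity = tr$severity,
      global_ns_scale = tr$global_ns_scale,
      n_wmh = tr$lesions$counts[["wmh"]],
      n_lacunes = tr$lesions$counts[["lacunes"]],
      n_cortical_infarcts = tr$lesions$counts[["cortical_infarcts"]],
      n_cmbs = tr$lesions$counts[["cmbs"]],
      n_lesions_total = total_lesion_count(tr$lesions),
      wmh_volume_ml = tr$lesions$wmh_volume_ml,
      cognition = tr$covariates$cognition,
      atrophy_grade = tr$covariates$atrophy_grade,
      hippocampal_volume = tr$covariates$hippocampal_volume,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
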
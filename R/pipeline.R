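## End-to-end pipeline: simulate -> select -> train -> estimate NS ->
## quantify -> evaluate -> associate, with deterministic artifacts.

#' Pipeline configuration
#'
#' Assembles and validates the full configuration: cohort size, generator
#' settings, translator settings, metric and association settings and the
#' global seed. Unknown keys are rejected with the offending key named.
#'
#' @param ... named overrides. `phantom` and `model` accept nested lists
#'   passed on to [phantom_config()] and [translator_config()].
#' @return A named list of class `sabl_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n = 40L,
    seed = 1L,
    select_n = 40L,
    n_eval = 6L,
    zero_burden_training_cohort = FALSE,
    phantom = list(),
    model = list(),
    erode_wm = 2L,
    hi_bins = 64L,
    markers = c("suvr_global", "sabl", "abl", "ns_gm"),
    covariates = c("cognition", "atrophy_grade", "hippocampal_volume",
                   "n_lesions_total", "wmh_volume_ml"),
    write_volumes = FALSE
  )
  override <- list(...)
  if (length(override) == 1L && is.null(names(override)) && is.list(override[[1]]) &&
      !inherits(override[[1]], "sabl_pipeline_config")) {
    override <- override[[1]]
  }
  if (length(override)) {
    bad <- setdiff(names(override), names(cfg))
    if (length(bad)) stop("unknown pipeline setting(s): ", paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(override)] <- override
  }
  # validate nested sections by instantiating them
  invisible(do.call(phantom_config, cfg$phantom))
  invisible(do.call(translator_config, cfg$model))
  structure(cfg, class = "sabl_pipeline_config")
}

#' Small demonstration configuration
#'
#' A 40-phantom cohort on a 32-voxel grid with a tiny translator, sized so
#' the full pipeline runs in about a minute.
#'
#' @param seed global seed.
#' @return An `sabl_pipeline_config`.
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    n = 40L, seed = as.integer(seed), select_n = 20L, n_eval = 4L,
    phantom = list(grid = c(32L, 32L, 32L)),
    model = list(channels = 4, epochs = 3, seed = as.integer(seed))
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipeline_config()].
#' @return An `sabl_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(raw)
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[3]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[sabl] stage %-12s %7.1f s", name, proc.time()[3] - t0))
  res
}

#' Per-subject biomarker table
#'
#' Joins, for every subject, the global SUVr, the NS-subtraction biomarker
#' SAbL, the two-template coefficients (AbL, ns), the mean NS estimate in
#' cortical GM, and the generator ground truth and covariates.
#'
#' @param cohort an `sabl_cohort`.
#' @param ns_estimates list of NS estimate volumes, one per subject.
#' @param templates optional `sabl_templates` for the AbL fit.
#' @return data.frame, one row per subject.
#' @export
biomarker_table <- function(cohort, ns_estimates, templates = NULL) {
  tab <- cohort_table(cohort)
  rows <- lapply(seq_along(cohort$subjects), function(i) {
    v <- cohort$subjects[[i]]$volumes
    suvr <- compute_suvr(v$pet, v$masks$reference)
    sg <- roi_mean(suvr$data, v$masks$gm)
    sb <- compute_sabl(suvr, ns_estimates[[i]], v$masks$gm)
    out <- data.frame(suvr_global = sg, sabl = sb$sabl,
                      ns_gm = roi_mean(ns_estimates[[i]], v$masks$gm))
    if (!is.null(templates)) {
      f <- fit_abl(suvr, templates)
      out$abl <- f$abl
      out$ns_coeff <- f$ns_coeff
    }
    out
  })
  cbind(tab, do.call(rbind, rows))
}

#' Run the full pipeline
#'
#' Simulates a phantom cohort, selects the lowest-SUVr subset, splits it
#' into training and evaluation groups, trains the MRI-to-NS translator,
#' predicts NS maps for every subject, computes SAbL and the two-template
#' AbL, evaluates the NS estimates region-wise on the held-out subjects,
#' and runs the biomarker association analysis. All artifacts are written
#' under `out_dir` (CSV tables and a JSON run manifest; volumes optionally).
#'
#' @param config an `sabl_pipeline_config`.
#' @param out_dir output directory.
#' @return Invisibly, a list with the in-memory artifacts (`biomarkers`,
#'   `metrics`, `assoc`, `model`, `selection`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "sabl_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pcfg_args <- config$phantom
  if (isTRUE(config$zero_burden_training_cohort)) {
    pcfg_args$p_high <- 0
    pcfg_args$burden_low_sd <- 0
  }
  pcfg <- do.call(phantom_config, pcfg_args)

  cohort <- run_stage("simulate", generate_cohort(config$n, pcfg, config$seed))
  if (isTRUE(config$write_volumes)) run_stage("write", write_cohort(cohort, file.path(out_dir, "cohort")))

  suvr_globals <- vapply(cohort$subjects, function(s)
    roi_mean(s$volumes$pet, s$volumes$masks$gm), numeric(1))
  sel <- run_stage("select", {
    pool <- select_training_set(suvr_globals, config$select_n)
    split <- split_train_eval(pool, config$n_eval, derive_seed(config$seed, 2L, 51L))
    list(pool = pool, train = split$train, eval = split$eval)
  })

  model <- run_stage("train", {
    margs <- config$model
    if (is.null(margs$seed)) margs$seed <- derive_seed(config$seed, 3L, 52L)
    mcfg <- do.call(translator_config, margs)
    pairs <- lapply(sel$train, function(i) list(
      volumes = cohort$subjects[[i]]$volumes,
      target = cohort$subjects[[i]]$volumes$pet))
    train_translator(pairs, mcfg)
  })

  ns_estimates <- run_stage("estimate-ns", lapply(cohort$subjects, function(s)
    predict_ns(model, s$volumes)))

  templates <- run_stage("templates", {
    pool <- lapply(cohort$subjects, function(s) s$volumes$pet)
    build_templates(pool, cohort$subjects[[1]]$volumes$masks$wb,
                    gm_mask = cohort$subjects[[1]]$volumes$masks$gm)
  })

  biomarkers <- run_stage("quantify", biomarker_table(cohort, ns_estimates, templates))

  metrics <- run_stage("evaluate", {
    rows <- lapply(sel$eval, function(i) {
      rep <- region_report(ns_estimates[[i]], cohort$subjects[[i]]$truth$ns_suvr,
                           cohort$subjects[[i]]$volumes$masks,
                           erode_wm = config$erode_wm, n_bins = config$hi_bins)
      cbind(subject_id = sprintf("sub-%03d", i), rep)
    })
    do.call(rbind, rows)
  })

  assoc <- run_stage("associate", {
    markers <- intersect(config$markers, names(biomarkers))
    association_table(biomarkers, markers, config$covariates)
  })

  utils::write.csv(biomarkers, file.path(out_dir, "biomarkers.csv"), row.names = FALSE)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(assoc, file.path(out_dir, "assoc.csv"), row.names = FALSE)
  utils::write.csv(cohort_table(cohort), file.path(out_dir, "cohort.csv"), row.names = FALSE)

  manifest <- list(
    package = "sabl",
    version = as.character(utils::packageVersion("sabl")),
    seed = config$seed,
    config = unclass(config),
    selection = sel,
    final_training_loss = model$loss_history[length(model$loss_history)]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(biomarkers = biomarkers, metrics = metrics, assoc = assoc,
                 model = model, selection = sel, cohort = cohort,
                 ns_estimates = ns_estimates))
}
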
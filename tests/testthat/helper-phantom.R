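# Shared small fixtures, built once per test run. 32^3 is the smallest grid
# the anatomy model supports; it keeps the unit tests fast.

small_grid <- c(32L, 32L, 32L)

small_config <- function(...) phantom_config(grid = small_grid, ...)

# memoised single phantom subject used by several files
.fixtures <- new.env(parent = emptyenv())

fixture_subject <- function() {
  if (is.null(.fixtures$subj)) {
    cfg <- small_config()
    a <- generate_anatomy(small_grid, 0.3, 42L)
    les <- inject_cevd(a, 0.5, 43L, cfg)
    tr <- render_truth(a, les, 0.6, 0.95, 44L, cfg)
    v <- render_observed(a, tr, cfg$psf_fwhm_mm, cfg$pet_noise_sd, 45L, cfg)
    tr$ns_suvr <- attr(v, "ns_suvr")
    .fixtures$subj <- list(anatomy = a, lesions = les, truth = tr, volumes = v)
  }
  .fixtures$subj
}

fixture_cohort <- function(n = 6, seed = 7L) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_cohort(n, small_config(), seed)
  }
  .fixtures[[key]]
}
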
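# Phantom generator: anatomy construction, lesion placement, ground-truth
# rendering and the observation model.

test_that("anatomy contains all compartments with sensible proportions", {
  a <- generate_anatomy(c(48, 48, 48), 0.3, 1)
  lab <- a$labels
  expect_setequal(sort(unique(as.vector(lab))), 0:6)
  brain <- sum(lab > 0)
  for (l in 1:6) expect_gt(sum(lab == l) / brain, 0.01)
  # cortical GM shell is adjacent to WM (forms a shell around it)
  wm_d <- !sabl:::erode3d(lab != 3, 1) & lab != 3  # voxels bordering WM
  expect_gt(sum(lab[wm_d] == 2), 0)
  # reference region spatially disjoint from cortical GM
  ref_d <- !sabl:::erode3d(lab != 5, 1)
  expect_equal(sum(lab[ref_d & lab != 5] == 2), 0)
})

test_that("atrophy thins the cortical GM monotonically at fixed seed", {
  counts <- vapply(c(0, 0.4, 0.8), function(atr)
    sum(generate_anatomy(small_grid, atr, 1)$labels == 2), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[3])
})

test_that("anatomy is deterministic and rejects too-small grids", {
  a1 <- generate_anatomy(small_grid, 0.3, 5)
  a2 <- generate_anatomy(small_grid, 0.3, 5)
  expect_identical(a1$labels, a2$labels)
  expect_error(generate_anatomy(c(16, 48, 48), 0, 1), "grid too small")
})

test_that("lesion injection obeys placement constraints and severity scaling", {
  a <- generate_anatomy(small_grid, 0.2, 3)
  cfg <- small_config()
  l0 <- inject_cevd(a, 0, 4, cfg)
  expect_true(all(l0$counts == 0))
  expect_equal(nrow(l0$wmh$centers), 0)

  les <- inject_cevd(a, 0.8, 4, cfg)
  expect_equal(unname(les$counts),
               unname(vapply(c("wmh", "lacunes", "cortical_infarcts", "cmbs"),
                             function(cl) nrow(les[[cl]]$centers), integer(1))))
  if (les$counts[["wmh"]] > 0) {
    for (k in seq_len(les$counts[["wmh"]])) {
      ctr <- round(les$wmh$centers[k, ])
      expect_equal(a$labels[ctr[1], ctr[2], ctr[3]], 3L)  # WM
    }
  }
  if (les$counts[["cmbs"]] > 0) {
    expect_true(all(les$cmbs$radii <= 1))
  }
  # counts increase with severity in expectation (Monte Carlo over seeds)
  mean_count <- function(sev) mean(vapply(1:50, function(s)
    sum(inject_cevd(a, sev, s, cfg)$counts), numeric(1)))
  expect_gt(mean_count(1), mean_count(0.2))
})

test_that("ground truth: NS is WM-dominant, scales with global_ns_scale, lesions reduce it", {
  a <- generate_anatomy(small_grid, 0.2, 3)
  cfg <- small_config()
  les0 <- inject_cevd(a, 0, 4, cfg)
  t1x <- render_truth(a, les0, 0.5, 1.0, 5, cfg)
  expect_gt(mean(t1x$ns_true[a$labels == 3]), mean(t1x$ns_true[a$labels == 2]))
  # specific uptake: zero outside cortical GM, zero in the reference region
  expect_true(all(t1x$specific_true[a$labels != 2] == 0))
  expect_true(all(t1x$specific_true[a$labels == 5] == 0))
  # burden = 0 gives an identically zero specific map
  t0 <- render_truth(a, les0, 0, 1.0, 5, cfg)
  expect_true(all(t0$specific_true == 0))
  # specific map scales linearly with burden
  t2 <- render_truth(a, les0, 1.0, 1.0, 5, cfg)
  expect_equal(t2$specific_true * 0.5, t1x$specific_true)
  # doubling the NS scale doubles NS over the scaled (supratentorial) tissue
  # and leaves the cerebellar reference untouched
  td <- render_truth(a, les0, 0.5, 2.0, 5, cfg)
  cer <- a$labels %in% 2:4
  expect_equal(td$ns_true[cer], 2 * t1x$ns_true[cer])
  expect_equal(td$ns_true[a$labels == 5], t1x$ns_true[a$labels == 5])

  # paired lesion-free twin comparison: NS drops inside each lesion class
  lesA <- inject_cevd(a, 0.9, 11, cfg)
  tA <- render_truth(a, lesA, 0.5, 1.0, 5, cfg)
  for (cls in c("wmh", "lacunes", "cortical_infarcts")) {
    n <- lesA$counts[[cls]]
    if (n == 0) next
    vox <- unique(unlist(lapply(seq_len(n), function(k)
      sabl:::sphere_indices(dim(a$labels), lesA[[cls]]$centers[k, ], lesA[[cls]]$radii[k]))))
    vox <- vox[a$labels[vox] > 0]
    expect_lt(mean(tA$ns_true[vox]), mean(t1x$ns_true[vox]))
  }
  # microbleeds leave NS unchanged
  only_cmb <- lesA
  for (cls in c("wmh", "lacunes", "cortical_infarcts")) {
    only_cmb[[cls]] <- list(centers = matrix(numeric(0), 0, 3), radii = numeric(0))
    only_cmb$counts[[cls]] <- 0L
  }
  tC <- render_truth(a, only_cmb, 0.5, 1.0, 5, cfg)
  expect_equal(tC$ns_true, t1x$ns_true)
})

test_that("observation model: normalization contract and spill-in", {
  a <- generate_anatomy(small_grid, 0.2, 3)
  cfg <- small_config()
  les <- inject_cevd(a, 0, 4, cfg)
  tr <- render_truth(a, les, 0, 1.05, 5, cfg)
  # psf = 0, noise = 0: pet equals ns_true / reference mean exactly
  v0 <- render_observed(a, tr, 0, 0, 6, cfg)
  r <- mean(tr$ns_true[a$labels == 5])
  expect_equal(v0$pet, tr$ns_true / r, tolerance = 1e-12)
  expect_lt(abs(mean(v0$pet[v0$masks$reference]) - 1), 1e-6)
  # with blur, WM signal spills into adjacent GM: the GM rim next to WM
  # shows higher uptake than unblurred truth at the same voxels
  vb <- render_observed(a, tr, 6, 0, 6, cfg)
  rim <- (!sabl:::erode3d(a$labels != 3, 2)) & (a$labels == 2)
  expect_gt(mean(vb$pet[rim]), mean(v0$pet[rim]))
  # masks are consistent with labels and nested in the whole-brain mask
  expect_identical(vb$masks$gm, a$labels == 2)
  expect_true(all(vb$masks$wb[vb$masks$gm]))
  expect_true(any(vb$masks$reference))
  # lesion MRI contrast: WMH are FLAIR-bright and T1-dark
  lesw <- inject_cevd(a, 1, 12, cfg)
  if (lesw$counts[["wmh"]] > 0) {
    trw <- render_truth(a, lesw, 0, 1, 5, cfg)
    vw <- render_observed(a, trw, 0, 0, 6, cfg)
    vn <- render_observed(a, render_truth(a, inject_cevd(a, 0, 1, cfg), 0, 1, 5, cfg), 0, 0, 6, cfg)
    vox <- unlist(lapply(seq_len(lesw$counts[["wmh"]]), function(k)
      sabl:::sphere_indices(dim(a$labels), lesw$wmh$centers[k, ], lesw$wmh$radii[k])))
    vox <- vox[a$labels[vox] == 3]
    expect_gt(mean(vw$flair[vox]), mean(vn$flair[vox]))
    expect_lt(mean(vw$t1[vox]), mean(vn$t1[vox]))
  }
})

test_that("cohort generation is deterministic and respects the burden mixture", {
  c1 <- generate_cohort(4, small_config(), 7)
  c2 <- generate_cohort(4, small_config(), 7)
  expect_identical(c1$subjects[[3]]$volumes$pet, c2$subjects[[3]]$volumes$pet)
  expect_identical(cohort_table(c1), cohort_table(c2))
  expect_error(generate_cohort(1, small_config(), 7), "at least 2")

  c0 <- generate_cohort(6, small_config(p_high = 0, burden_low_sd = 0), 8)
  expect_true(all(cohort_table(c0)$burden == 0))

  # fraction of low-burden subjects within the binomial 99% CI of 0.7
  tab <- cohort_table(fixture_cohort(n = 100, seed = 19L))
  n_low <- sum(tab$burden < 0.2)
  ci <- qbinom(c(0.005, 0.995), 100, 0.7)
  expect_gte(n_low, ci[1])
  expect_lte(n_low, ci[2])
})

test_that("cohort covariates carry the designed associations with burden", {
  tab <- cohort_table(fixture_cohort(n = 100, seed = 19L))
  s1 <- spearman(tab$cognition, tab$burden)
  s2 <- spearman(tab$hippocampal_volume, tab$burden)
  expect_lt(s1$rho, 0)
  expect_lt(s2$rho, 0)
  expect_lt(s1$p, 0.01)
  expect_lt(s2$p, 0.01)
})

test_that("generator settings are validated by name", {
  expect_error(phantom_config(not_a_setting = 1), "not_a_setting")
})
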
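# Brute-force oracles for the four image-similarity metrics. Each oracle is
# an independent re-derivation (explicit loops / two-pass moments), kept
# deliberately naive.

oracle_mse <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  s / length(x)
}

oracle_ssim <- function(x, y, L) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- 0; vy <- 0; cxy <- 0
  for (i in seq_len(n)) {
    vx <- vx + (x[i] - mx)^2
    vy <- vy + (y[i] - my)^2
    cxy <- cxy + (x[i] - mx) * (y[i] - my)
  }
  vx <- vx / n; vy <- vy / n; cxy <- cxy / n
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  (2 * mx * my + c1) * (2 * cxy + c2) / ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

oracle_hi <- function(x, y, n_bins) {
  lo <- min(c(x, y)); hi <- max(c(x, y))
  w <- (hi - lo) / n_bins
  cx <- numeric(n_bins); cy <- numeric(n_bins)
  for (v in x) cx[min(n_bins, max(1, ceiling((v - lo) / w)))] <-
    cx[min(n_bins, max(1, ceiling((v - lo) / w)))] + 1
  for (v in y) cy[min(n_bins, max(1, ceiling((v - lo) / w)))] <-
    cy[min(n_bins, max(1, ceiling((v - lo) / w)))] + 1
  sum(pmin(cx / length(x), cy / length(y)))
}

test_that("scalar metrics reproduce hand-computed values", {
  expect_equal(mse(c(1, 2), c(1, 4)), 2.0)
  expect_equal(mre_pct(c(1.9, 1.9), c(2.0, 2.0)), 5.0)
  expect_equal(mre_pct(rep(2.2, 4), rep(2.0, 4)), -10.0)
  expect_equal(cohort_mre(c(5, -5)), 5.0)
  expect_equal(cohort_mre(c(0, 0, 0)), 0)
  # constant-input SSIM: sigma terms vanish and c2 cancels
  a <- 1.3; b <- 0.8; L <- 2
  c1 <- (0.01 * L)^2
  expect_equal(ssim(rep(a, 10), rep(b, 10), L = L), (2 * a * b + c1) / (a^2 + b^2 + c1))
})

test_that("identical inputs give (mse, ssim, mre, hi) = (0, 1, 0, 1) exactly", {
  x <- rnorm(500)
  expect_identical(mse(x, x), 0)
  expect_equal(ssim(x, x), 1)
  expect_identical(mre_pct(x, x), 0)
  expect_equal(histogram_intersection(x, x), 1)
})

test_that("metrics match independent brute-force oracles on random pairs", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(50:400, 1)
    x <- rnorm(n, mean = runif(1, -1, 2), sd = runif(1, 0.1, 2))
    y <- x + rnorm(n, sd = runif(1, 0.01, 1))
    L <- max(c(x, y)) - min(c(x, y))
    expect_lt(abs(mse(x, y) - oracle_mse(x, y)), 1e-10)
    expect_lt(abs(ssim(x, y) - oracle_ssim(x, y, L)), 1e-10)
    expect_lt(abs(mre_pct(x, y) - 100 * (mean(y) - mean(x)) / mean(y)), 1e-10)
    expect_lt(abs(histogram_intersection(x, y, 32) - oracle_hi(x, y, 32)), 1e-10)
  }
})

test_that("metrics are invariant under voxel permutation and have the stated symmetries", {
  set.seed(12)
  x <- rnorm(300); y <- rnorm(300, 0.5)
  p <- sample(300)
  L <- max(c(x, y)) - min(c(x, y))
  expect_equal(mse(x[p], y[p]), mse(x, y))
  expect_equal(ssim(x[p], y[p], L), ssim(x, y, L))
  expect_equal(mre_pct(x[p], y[p]), mre_pct(x, y))
  expect_equal(histogram_intersection(x[p], y[p]), histogram_intersection(x, y))
  # symmetry
  expect_equal(mse(x, y), mse(y, x))
  expect_equal(histogram_intersection(x, y), histogram_intersection(y, x))
  expect_equal(ssim(x, y, L), ssim(y, x, L))
  # role swap changes the MRE sign up to scaling by the ratio of means
  expect_equal(mre_pct(y, x), -mre_pct(x, y) * mean(y) / mean(x))
})

test_that("ssim is continuous at the identity: ssim(x, a*x + b) -> 1 as a -> 1, b -> 0", {
  set.seed(13)
  x <- rnorm(1000, 2, 0.5)
  for (eps in c(1e-6, -1e-6)) {
    expect_gt(ssim(x, (1 + eps) * x + eps, L = diff(range(x))), 1 - 1e-6)
  }
})

test_that("histogram intersection separates disjoint distributions and stays in [0, 1]", {
  set.seed(14)
  x <- runif(400, 0, 1); y <- runif(400, 10, 11)
  hi <- histogram_intersection(x, y, 64)
  expect_equal(hi, oracle_hi(x, y, 64))
  expect_lt(hi, 0.05)
  for (rep in 1:20) {
    a <- rnorm(100); b <- rnorm(100, runif(1, -2, 2))
    h <- histogram_intersection(a, b)
    expect_gte(h, 0)
    expect_lte(h, 1)
  }
  # degenerate range convention
  expect_equal(histogram_intersection(rep(2, 5), rep(2, 7)), 1)
})

test_that("region_report composes the scalar metrics and erodes the WM mask", {
  s <- fixture_subject()
  est <- s$volumes$pet * 1.05 + 0.02
  truth <- s$volumes$pet
  rep1 <- region_report(est, truth, s$volumes$masks, erode_wm = 2, n_bins = 32)
  expect_setequal(rep1$region, c("WB", "GM", "WM", "reference"))
  # composition oracle: extract the vectors and call the scalar ops
  wm_eroded <- sabl:::erode3d(s$volumes$masks$wm, 2)
  expect_lt(sum(wm_eroded), sum(s$volumes$masks$wm))
  for (rn in c("WB", "GM", "WM", "reference")) {
    m <- switch(rn, WB = s$volumes$masks$wb, GM = s$volumes$masks$gm,
                WM = wm_eroded, reference = s$volumes$masks$reference)
    row <- rep1[rep1$region == rn, ]
    expect_equal(row$n_voxels, sum(m))
    expect_equal(row$mse, mse(est[m], truth[m]))
    expect_equal(row$ssim, ssim(est[m], truth[m]))
    expect_equal(row$mre_pct, mre_pct(est[m], truth[m]))
    expect_equal(row$hi, histogram_intersection(est[m], truth[m], 32))
  }
  # identity estimate reports (0, 1, 0, 1) everywhere
  rep0 <- region_report(truth, truth, s$volumes$masks)
  expect_true(all(rep0$mse == 0))
  expect_true(all(abs(rep0$ssim - 1) < 1e-12))
  expect_true(all(rep0$mre_pct == 0))
  expect_true(all(rep0$hi == 1))
})

test_that("metric error conditions are reported", {
  expect_error(mse(1:3, 1:4), "length")
  expect_error(mre_pct(c(1, 2), c(-1, 1)), "zero")
  expect_error(ssim(c(1, 2), c(3, 4), L = -1), "dynamic range")
  expect_error(cohort_mre(numeric(0)), "no subject")
  s <- fixture_subject()
  expect_error(region_report(s$volumes$pet, s$volumes$pet, s$volumes$masks,
                             erode_wm = 50), "WM")
})
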
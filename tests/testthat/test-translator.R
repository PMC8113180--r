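# Convolution kernels against a brute-force direct-convolution oracle,
# numerical gradient checks of the full network, and the training contract.

brute_conv3d <- function(x, W, b) {
  d <- dim(x)[1:3]; Cin <- dim(x)[4]; Cout <- ncol(W)
  Wa <- array(W, c(3, 3, 3, Cin, Cout))
  out <- array(0, c(d, Cout))
  for (co in 1:Cout) for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- b[co]
    for (ci in 1:Cin) for (a in -1:1) for (bb in -1:1) for (cc in -1:1) {
      ii <- i + a; jj <- j + bb; kk <- k + cc
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && kk >= 1 && kk <= d[3])
        acc <- acc + Wa[a + 2, bb + 2, cc + 2, ci, co] * x[ii, jj, kk, ci]
    }
    out[i, j, k, co] <- acc
  }
  out
}

test_that("compiled 3D convolution matches the brute-force oracle", {
  withr::with_seed(61, {
    for (rep in 1:3) {
      d <- sample(3:6, 3, replace = TRUE)
      Cin <- sample(1:3, 1); Cout <- sample(1:3, 1)
      x <- array(rnorm(prod(d) * Cin), c(d, Cin))
      W <- matrix(rnorm(27 * Cin * Cout), 27 * Cin, Cout)
      b <- rnorm(Cout)
      y <- sabl:::conv3d_forward(x, W, b)
      expect_lt(max(abs(y - as.vector(brute_conv3d(x, W, b)))), 1e-12)
    }
  })
})

test_that("network gradients match central finite differences", {
  withr::with_seed(62, {
    d <- c(8L, 8L, 8L)
    cfg <- translator_config(n_levels = 2, channels = 3, n_hidden = 1,
                             epochs = 1, seed = 3)
    cin <- sabl:::branch_channels(cfg)[1]
    x <- array(rnorm(prod(d) * cin), c(d, cin))
    x[1:2, , , ] <- 0
    tgt <- array(rnorm(prod(d)), d)
    m <- array(runif(prod(d)) > 0.3, d)
    params <- sabl:::init_params(cfg, d, 0.5)
    for (l in 1:2) params[[l]]$gate$Wo <- matrix(rnorm(8, 0, 0.2), 1, 8)
    lossfun <- function(p) {
      fw <- sabl:::translator_forward(p, x, cfg)
      sum(((fw$pred - tgt) * m)^2) / sum(m)
    }
    fw <- sabl:::translator_forward(params, x, cfg, keep_cache = TRUE)
    g <- sabl:::translator_backward(params, cfg, fw$cache,
                                    2 * (fw$pred - tgt) * m / sum(m))
    errs <- c()
    for (rep in 1:30) {
      l <- sample(2, 1)
      if (runif(1) < 0.7) {
        j <- sample(3, 1); nm <- sample(c("W", "b"), 1)
        p0 <- params[[l]]$conv[[j]][[nm]]; ana <- g[[l]]$conv[[j]][[nm]]
        setp <- function(p, k, v) { p[[l]]$conv[[j]][[nm]][k] <- v; p }
      } else {
        nm <- sample(c("Wg", "bg", "Wo"), 1)
        p0 <- params[[l]]$gate[[nm]]; ana <- g[[l]]$gate[[nm]]
        setp <- function(p, k, v) { p[[l]]$gate[[nm]][k] <- v; p }
      }
      k <- sample(length(p0), 1); h <- 1e-6
      num <- (lossfun(setp(params, k, p0[k] + h)) -
                lossfun(setp(params, k, p0[k] - h))) / (2 * h)
      errs <- c(errs, abs(num - ana[k]) / max(1e-7, abs(num) + abs(ana[k])))
    }
    # median over probes is robust to occasional ReLU kink crossings of the
    # finite-difference step
    expect_lt(median(errs), 1e-7)
    expect_lt(mean(errs > 1e-3), 0.2)
  })
})

make_tiny_pairs <- function(n, d, target_fun, seed = 63) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      wb <- array(TRUE, d)
      t1 <- array(runif(prod(d), 0.4, 1), d)
      fl <- array(runif(prod(d), 0.2, 0.8), d)
      vols <- list(t1 = t1, flair = fl, masks = list(wb = wb))
      list(volumes = vols, target = target_fun(t1, fl))
    })
  })
}

test_that("training learns a constant target and the loss decreases", {
  d <- c(16L, 16L, 16L)
  pairs <- make_tiny_pairs(4, d, function(t1, fl) array(1.4, dim(t1)))
  cfg <- translator_config(n_levels = 1, channels = 4, n_hidden = 0,
                           epochs = 30, batch_size = 2, patch_size = NULL,
                           learning_rate = 3e-3, seed = 5)
  model <- train_translator(pairs, cfg)
  expect_length(model$loss_history, 30)
  expect_true(all(is.finite(model$loss_history)))
  # mean loss over the last 10% of epochs does not exceed the first epoch
  expect_lte(mean(tail(model$loss_history, 3)), model$loss_history[1])
  expect_lt(tail(model$loss_history, 1), 0.25 * model$loss_history[1])
  pred <- predict_ns(model, pairs[[1]]$volumes)
  expect_identical(dim(pred), d)
  expect_true(all(abs(pred[3:14, 3:14, 3:14] - 1.4) < 0.05 * 1.4))
  expect_true(all(pred >= 0))
})

test_that("training is deterministic given data and seed", {
  d <- c(16L, 16L, 16L)
  pairs <- make_tiny_pairs(3, d, function(t1, fl) t1 + 0.5 * fl)
  cfg <- translator_config(n_levels = 2, channels = 3, epochs = 4,
                           patch_size = 8, seed = 9)
  m1 <- train_translator(pairs, cfg)
  m2 <- train_translator(pairs, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
})

test_that("training rejects shape mismatches and missing channels", {
  d <- c(16L, 16L, 16L)
  pairs <- make_tiny_pairs(2, d, function(t1, fl) t1)
  bad <- pairs
  bad[[2]]$target <- array(0, c(8, 8, 8))
  expect_error(train_translator(bad, translator_config(epochs = 1)), "grid mismatch")
  cfg <- translator_config(epochs = 1, patch_size = 8, seed = 2)
  model <- train_translator(pairs, cfg)
  subj <- pairs[[1]]$volumes
  subj$flair <- NULL
  expect_error(predict_ns(model, subj), "missing input channel")
})

test_that("predicted NS level follows the phantom's global NS scale", {
  # two subjects differing only in global_ns_scale; majority vote over seeds
  cohort <- fixture_cohort(n = 10, seed = 3L)
  cfg <- small_config()
  pairs <- lapply(cohort$subjects, function(s)
    list(volumes = s$volumes, target = s$volumes$pet))
  mcfg <- translator_config(n_levels = 2, channels = 6, epochs = 60,
                            batch_size = 2, patch_size = 16, learning_rate = 4e-3,
                            seed = 31)
  model <- train_translator(pairs, mcfg)
  votes <- vapply(1:10, function(sd) {
    a <- generate_anatomy(small_grid, 0.3, sd)
    les <- inject_cevd(a, 0.2, sd + 100, cfg)
    gm_means <- vapply(c(1.0, 1.3), function(g) {
      tr <- render_truth(a, les, 0, g, sd + 200, cfg)
      v <- render_observed(a, tr, cfg$psf_fwhm_mm, cfg$pet_noise_sd, sd + 300, cfg)
      mean(predict_ns(model, v)[v$masks$gm])
    }, numeric(1))
    gm_means[2] > gm_means[1]
  }, logical(1))
  expect_gt(mean(votes), 0.5)
})

test_that("split_train_eval is disjoint, exhaustive and deterministic", {
  idx <- 11:30
  s1 <- split_train_eval(idx, 5, seed = 4)
  s2 <- split_train_eval(idx, 5, seed = 4)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$eval), 0)
  expect_setequal(c(s1$train, s1$eval), idx)
  s0 <- split_train_eval(idx, 0, seed = 4)
  expect_identical(s0$train, idx)
  expect_length(s0$eval, 0)
  expect_error(split_train_eval(idx, 20, seed = 1), "smaller")
})
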
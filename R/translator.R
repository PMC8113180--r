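## MRI -> nonspecific-PET image translation.
##
## A small multi-scale 3D convolutional regression network maps structural
## MRI (T1 and/or FLAIR, z-scored per volume inside the brain mask) to the
## subject's NS uptake image in SUVr units. The network has `n_levels`
## parallel branches operating at dyadically downsampled resolutions; each
## branch is a short stack of 3x3x3 convolutions with ReLU activations and a
## linear single-channel output, and the branch outputs are fused by
## summation after nearest-neighbour upsampling. Training minimizes the
## voxel-wise mean squared error inside the brain mask with the Adam
## optimizer; everything is deterministic given the data and the seed.

#' Translator model configuration
#'
#' @param inputs character subset of `c("t1", "flair")`; both = multimodal.
#' @param n_levels number of parallel resolution branches (>= 1); grid
#'   dimensions must be divisible by `2^(n_levels - 1)`.
#' @param channels hidden channel width of each branch.
#' @param n_hidden number of hidden channel-preserving convolutions per
#'   branch (each branch has `n_hidden + 2` convolutions in total).
#' @param epochs training epochs (>= 1).
#' @param batch_size subjects per optimizer step.
#' @param learning_rate Adam step size; decayed by `lr_decay` at 60% and 85%
#'   of the epoch schedule.
#' @param lr_decay multiplicative step-decay factor (1 = constant rate).
#' @param patch_size edge length of the random cubic crops used for
#'   training steps, or `NULL` to train on full volumes. Patch sampling is
#'   the standard way to train fully convolutional 3D networks: it
#'   decorrelates steps and cuts their cost, while inference still runs on
#'   the full grid. Must be divisible by `2^(n_levels - 1)`.
#' @param loss_margin voxels stripped from each patch face when computing
#'   the training loss, so zero-padding artifacts at crop borders do not
#'   drive the fit.
#' @param calibration if `TRUE` (default) the trained model carries a
#'   global calibration head: a ridge regression (fit on the training pairs
#'   only) from tissue-resolved global statistics of the normalized input
#'   channels to the log mean target uptake over the calibration mask
#'   (cortical GM when available). At inference the translated map is
#'   rescaled so its calibration-mask mean equals the predicted level,
#'   correcting the global uptake scale that a small convolutional network
#'   recovers only sluggishly. The head sees MRI-derived features only,
#'   never the subject's PET.
#' @param global_gate if `TRUE` (default) each branch carries a
#'   squeeze-and-excitation style global gate: per-channel means and
#'   standard deviations of the full-volume input feed a small tanh layer
#'   whose scalar output rescales the branch's predicted uptake. This gives
#'   the network a direct multiplicative pathway from the subject's global
#'   tissue contrast (which encodes the myelin / NS level) to the predicted
#'   uptake scale, a product structure that plain additive convolutions
#'   learn only very slowly.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @param loss loss function; only `"mse"` (brain-masked) is available.
#' @param intensity_normalization input normalization. The default
#'   `"mean_per_volume"` divides each volume by its brain-mask mean, which
#'   preserves the inter-subject tissue-contrast ratios that carry the
#'   myelin (and hence NS-level) information; `"zscore_per_volume"`
#'   standardizes mean and dispersion and is kept as an option.
#' @return A named list of class `sabl_translator_config`.
#' @export
translator_config <- function(inputs = c("t1", "flair"), n_levels = 2,
                              channels = 8, n_hidden = 1, epochs = 150,
                              batch_size = 2, learning_rate = 4e-3,
                              lr_decay = 0.3, patch_size = 24L,
                              loss_margin = 2L, context_sigma = 3,
                              calibration = TRUE, global_gate = TRUE,
                              seed = 1L, loss = "mse",
                              intensity_normalization = c("mean_per_volume",
                                                          "zscore_per_volume")) {
  inputs <- match.arg(inputs, c("t1", "flair"), several.ok = TRUE)
  stopifnot(length(inputs) >= 1, n_levels >= 1, channels >= 1, n_hidden >= 0,
            epochs >= 1, batch_size >= 1, learning_rate > 0, lr_decay > 0,
            is.null(patch_size) || patch_size >= 8, loss_margin >= 0)
  loss <- match.arg(loss)
  intensity_normalization <- match.arg(intensity_normalization)
  structure(list(inputs = inputs, n_levels = as.integer(n_levels),
                 channels = as.integer(channels), n_hidden = as.integer(n_hidden),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 patch_size = if (is.null(patch_size)) NULL else as.integer(patch_size),
                 loss_margin = as.integer(loss_margin),
                 context_sigma = context_sigma,
                 calibration = isTRUE(calibration),
                 global_gate = isTRUE(global_gate), seed = as.integer(seed),
                 loss = loss, intensity_normalization = intensity_normalization),
            class = "sabl_translator_config")
}

# Stack the configured input channels of one subject into a normalized 4D
# array; voxels outside the brain mask are zeroed. When context_sigma > 0 a
# Gaussian-smoothed copy of each modality (mask-normalized convolution, so
# background does not dilute the smoothing) is appended as an extra channel:
# it summarizes the regional tissue contrast, which is what carries the
# subject's global myelin / NS level.
prepare_input <- function(volumes, inputs, normalization = "mean_per_volume",
                          context_sigma = 3) {
  missing <- setdiff(inputs, names(volumes)[!vapply(volumes, is.null, logical(1))])
  if (length(missing)) {
    stop("subject is missing input channel(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- dim(volumes[[inputs[1]]])
  wb <- volumes$masks$wb
  nin <- length(inputs)
  nctx <- if (context_sigma > 0) nin else 0L
  x <- array(0, c(d, nin + nctx))
  wbd <- array(as.double(wb), d)
  wbs <- if (nctx) gaussian_blur3d(wbd, rep(context_sigma, 3)) else NULL
  for (k in seq_len(nin)) {
    v <- volumes[[inputs[k]]]
    stopifnot_shape(v, volumes[[inputs[1]]], "input channels")
    ch <- array(0, d)
    if (normalization == "zscore_per_volume") {
      ch <- zscore_in_mask(v, wb)
    } else {
      ch[wb] <- v[wb] / mean(v[wb])
    }
    x[, , , k] <- ch
    if (nctx) {
      sm <- gaussian_blur3d(ch * wbd, rep(context_sigma, 3))
      ctx <- array(0, d)
      ctx[wb] <- sm[wb] / pmax(wbs[wb], 1e-6)
      x[, , , nin + k] <- ctx
    }
  }
  x
}

# Channel sequence of one branch: Cin -> K -> (K ->)*n_hidden ... -> 1.
# Each modality contributes a native and, if configured, a smoothed context
# channel.
branch_channels <- function(config) {
  cin <- length(config$inputs) * (1L + (config$context_sigma > 0))
  c(cin, rep(config$channels, config$n_hidden + 1L), 1L)
}

init_params <- function(config, d, target_mean) {
  ch <- branch_channels(config)
  gate_hidden <- 8L
  withr::with_seed(config$seed, {
    lapply(seq_len(config$n_levels), function(l) {
      convs <- lapply(seq_len(length(ch) - 1L), function(j) {
        fan_in <- 27L * ch[j]
        W <- matrix(stats::rnorm(fan_in * ch[j + 1L], 0, sqrt(2 / fan_in)),
                    fan_in, ch[j + 1L])
        b <- if (j == length(ch) - 1L) rep(target_mean / config$n_levels, ch[j + 1L])
             else numeric(ch[j + 1L])
        list(W = W, b = b)
      })
      lvl <- list(conv = convs)
      if (config$global_gate) {
        # the gate rescales the branch output (a single channel); Wo starts
        # at zero so the gate is the identity at initialization
        lvl$gate <- list(
          Wg = matrix(stats::rnorm(gate_hidden * 2L * ch[1], 0, 0.3),
                      gate_hidden, 2L * ch[1]),
          bg = numeric(gate_hidden),
          Wo = matrix(0, ch[length(ch)], gate_hidden)
        )
      }
      lvl
    })
  })
}

# Generic utilities over nested parameter trees (lists with numeric leaves).
tree_zip <- function(a, b, f) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- tree_zip(a[[k]], b[[k]], f)
    a
  } else f(a, b)
}

tree_state <- function(p) {
  if (is.list(p)) lapply(p, tree_state) else list(m = p * 0, v = p * 0)
}

adam_step <- function(p, g, s, lr, bc1, bc2, beta1, beta2, eps) {
  if (is.list(p)) {
    for (k in seq_along(p)) {
      r <- adam_step(p[[k]], g[[k]], s[[k]], lr, bc1, bc2, beta1, beta2, eps)
      p[[k]] <- r$p
      s[[k]] <- r$s
    }
    return(list(p = p, s = s))
  }
  s$m <- beta1 * s$m + (1 - beta1) * g
  s$v <- beta2 * s$v + (1 - beta2) * g^2
  p <- p - lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
  list(p = p, s = s)
}

check_grid_levels <- function(config, d) {
  f <- 2^(config$n_levels - 1L)
  if (any(d %% f != 0)) {
    stop(sprintf("grid %s is not divisible by 2^(n_levels-1) = %d",
                 paste(d, collapse = "x"), f), call. = FALSE)
  }
  invisible(TRUE)
}

# Global-gate statistics: per-channel mean and standard deviation over the
# brain voxels of the full-resolution input. After per-volume mean
# normalization the means are ~1 for every subject, so the discriminative
# part is the SDs, which measure the tissue contrast that encodes the
# subject's myelin / NS level. Computed on the full volume (not the crop)
# so training and inference see the same statistics.
gate_stats <- function(x) {
  xf <- matrix(x, prod(dim(x)[1:3]), dim(x)[4])
  nz <- rowSums(abs(xf)) > 0
  xb <- xf[nz, , drop = FALSE]
  mu <- colMeans(xb)
  sdv <- sqrt(colMeans(sweep(xb, 2, mu)^2))
  c(mu, sdv)
}

# Global calibration features: tissue-resolved summary statistics of the
# normalized input channels, using the subject's parcellation masks (the
# surrounding pipeline assumes a parcellated MRI throughout), plus gross
# shape features (tissue volume fractions capture atrophy-driven spill
# geometry; the per-modality WM hyper/hypo-intensity fraction is a lesion
# load proxy). Falls back to the whole-brain mask when a tissue mask is
# absent. `n_native` is the number of leading (non-context) channels.
calib_stats <- function(x, masks, n_native = dim(x)[4]) {
  wb <- masks$wb
  wm <- if (!is.null(masks$wm) && any(masks$wm)) masks$wm else wb
  gm <- if (!is.null(masks$gm) && any(masks$gm)) masks$gm else wb
  ref <- if (!is.null(masks$reference) && any(masks$reference)) masks$reference else wb
  wme <- erode3d(wm, 2)
  if (!any(wme)) wme <- wm
  out <- c()
  for (k in seq_len(dim(x)[4])) {
    ch <- x[, , , k]
    v <- ch[wb]
    mw <- mean(ch[wm]); mg <- mean(ch[gm]); mr <- mean(ch[ref])
    out <- c(out, mw, mg, mr, mean(v), stats::sd(v),
             stats::quantile(v, c(0.1, 0.9), names = FALSE),
             mean(ch[wme]), log(max(mw, 1e-8) / max(mg, 1e-8)),
             log(max(mw, 1e-8) / max(mr, 1e-8)))
  }
  shape <- c(sum(gm) / sum(wb), sum(wm) / sum(wb))
  for (k in seq_len(n_native)) {
    ch <- x[, , , k]
    shape <- c(shape, mean(ch[wm] > mean(ch[gm])))
  }
  c(out, shape)
}

# Full forward pass; returns the fused prediction and, when keep_cache, the
# per-level per-layer inputs, ReLU masks and gate activations needed for
# backprop.
translator_forward <- function(params, x, config, keep_cache = FALSE,
                               gate_u = NULL) {
  d <- dim(x)[1:3]
  ch <- branch_channels(config)
  nlayer <- length(ch) - 1L
  pred <- array(0, d)
  cache <- if (keep_cache) vector("list", config$n_levels) else NULL
  if (config$global_gate && is.null(gate_u)) gate_u <- gate_stats(x)
  for (l in seq_len(config$n_levels)) {
    xl <- x
    if (l > 1) for (r in seq_len(l - 1L)) xl <- pool_avg2(xl)
    dl <- dim(xl)[1:3]
    lcache <- if (keep_cache) list(layers = vector("list", nlayer)) else NULL
    gate <- NULL
    if (config$global_gate) {
      gt <- params[[l]]$gate
      z <- tanh(as.vector(gt$Wg %*% gate_u) + gt$bg)
      gate <- 1 + as.vector(gt$Wo %*% z)
      if (keep_cache) lcache$gate <- list(u = gate_u, z = z, gate = gate)
    }
    h <- xl
    for (j in seq_len(nlayer)) {
      y <- conv3d_forward(h, params[[l]]$conv[[j]]$W, params[[l]]$conv[[j]]$b)
      y_pre <- NULL
      if (j == nlayer && !is.null(gate)) {
        y_pre <- y
        y <- y * gate
      }
      if (j < nlayer) {
        act <- y > 0
        y <- y * act
      } else act <- NULL
      if (keep_cache) lcache$layers[[j]] <- list(input = h, act = act, y_pre = y_pre)
      h <- y
      dim(h) <- c(dl, ch[j + 1L])
    }
    out <- h
    if (l > 1) for (r in seq_len(l - 1L)) out <- upsample_nearest2(out)
    pred <- pred + out[, , , 1]
    if (keep_cache) cache[[l]] <- lcache
  }
  list(pred = pred, cache = cache)
}

translator_backward <- function(params, config, cache, dpred) {
  ch <- branch_channels(config)
  nlayer <- length(ch) - 1L
  grads <- vector("list", config$n_levels)
  for (l in seq_len(config$n_levels)) {
    lc <- cache[[l]]
    dl <- dim(lc$layers[[1]]$input)[1:3]
    g <- dpred
    dim(g) <- c(dim(dpred), 1L)
    if (l > 1) for (r in seq_len(l - 1L)) g <- upsample_nearest2_adj(g)
    g <- matrix(g, prod(dl), 1L)
    lgrads <- list(conv = vector("list", nlayer))
    for (j in rev(seq_len(nlayer))) {
      if (j < nlayer) g <- g * lc$layers[[j]]$act
      if (j == nlayer && config$global_gate) {
        gc_ <- lc$gate
        gt <- params[[l]]$gate
        dgate <- colSums(g * lc$layers[[j]]$y_pre)
        g <- g * gc_$gate
        dz <- as.vector(crossprod(gt$Wo, dgate))
        dzpre <- dz * (1 - gc_$z^2)
        lgrads$gate <- list(
          Wg = dzpre %o% gc_$u,
          bg = dzpre,
          Wo = dgate %o% gc_$z
        )
      }
      bw <- conv3d_backward(g, lc$layers[[j]]$input, params[[l]]$conv[[j]]$W,
                            need_dx = j > 1)
      lgrads$conv[[j]] <- list(W = bw$dW, b = bw$db)
      if (j > 1) g <- matrix(bw$dx, prod(dl), ch[j])
    }
    # keep element order aligned with params[[l]]
    grads[[l]] <- if (config$global_gate) list(conv = lgrads$conv, gate = lgrads$gate)
                  else list(conv = lgrads$conv)
  }
  grads
}

#' Train the MRI-to-NS translation model
#'
#' @param pairs list of training pairs; each element is a list with
#'   `volumes` (an `sabl_subject` providing the configured input channels and
#'   the `wb` mask) and `target` (3D array, the NS PET image in SUVr units;
#'   in the intended use this is the observed SUVr image of a low-burden
#'   subject).
#' @param config a [translator_config()].
#' @return An object of class `sabl_translator`: `params`, `config`,
#'   `loss_history` (per-epoch mean brain-masked MSE), `grid`.
#' @export
train_translator <- function(pairs, config = translator_config()) {
  stopifnot(length(pairs) >= 2)
  d <- dim(pairs[[1]]$target)
  xs <- lapply(pairs, function(p) {
    stopifnot_shape(p$target, pairs[[1]]$target, "training targets")
    prepare_input(p$volumes, config$inputs, config$intensity_normalization,
                  config$context_sigma)
  })
  ts <- lapply(pairs, function(p) p$target)
  ms <- lapply(pairs, function(p) p$volumes$masks$wb)

  check_grid_levels(config, d)
  ps <- config$patch_size
  if (!is.null(ps)) {
    ps <- min(ps, min(d))
    f <- 2^(config$n_levels - 1L)
    ps <- as.integer((ps %/% f) * f)
    if (ps < 8) stop("patch_size too small for the requested n_levels", call. = FALSE)
  }
  target_mean <- mean(vapply(seq_along(pairs), function(i) mean(ts[[i]][ms[[i]]]), numeric(1)))
  us <- NULL
  gate_norm <- NULL
  if (config$global_gate) {
    U <- t(vapply(xs, gate_stats, numeric(2L * branch_channels(config)[1])))
    # standardize the gate statistics across the training cohort: the
    # informative part is the (small) between-subject variation, which
    # would otherwise be drowned by the constant component
    ctr <- colMeans(U)
    scl <- apply(U, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-8] <- 1
    gate_norm <- list(center = ctr, scale = scl)
    us <- lapply(seq_len(nrow(U)), function(i) (U[i, ] - ctr) / scl)
  }
  params <- init_params(config, d, target_mean)

  adam_s <- tree_state(params)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(pairs)
  loss_history <- numeric(config$epochs)

  # random cubic crop with enough brain in the loss region; deterministic
  # draws from the per-epoch stream
  sample_patch <- function(i) {
    mg <- config$loss_margin
    for (try in 1:25) {
      orig <- vapply(1:3, function(ax)
        if (d[ax] == ps) 1L else sample.int(d[ax] - ps + 1L, 1L), integer(1))
      sl <- lapply(1:3, function(ax) orig[ax]:(orig[ax] + ps - 1L))
      m <- ms[[i]][sl[[1]], sl[[2]], sl[[3]]]
      if (mg > 0) {
        keep <- array(FALSE, c(ps, ps, ps))
        keep[(mg + 1):(ps - mg), (mg + 1):(ps - mg), (mg + 1):(ps - mg)] <- TRUE
        m <- m & keep
      }
      if (sum(m) >= 0.05 * ps^3) {
        return(list(x = xs[[i]][sl[[1]], sl[[2]], sl[[3]], , drop = FALSE],
                    t = ts[[i]][sl[[1]], sl[[2]], sl[[3]]], m = m))
      }
    }
    NULL
  }

  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      config$lr_decay^((epoch > 0.6 * config$epochs) + (epoch > 0.85 * config$epochs))
    epoch_rng <- derive_seed(config$seed, epoch, 41L)
    ep_losses <- rep(NA_real_, n)
    pos <- 0L
    batches <- withr::with_seed(epoch_rng, {
      ord <- sample.int(n)
      crops <- if (is.null(ps)) NULL else lapply(seq_len(n), sample_patch)
      list(ord = split(ord, ceiling(seq_along(ord) / config$batch_size)), crops = crops)
    })
    crops <- batches$crops
    for (batch in batches$ord) {
      gacc <- NULL
      for (i in batch) {
        if (is.null(ps)) {
          xi <- xs[[i]]; ti <- ts[[i]]; mi <- ms[[i]]
        } else {
          cr <- crops[[i]]
          if (is.null(cr)) next
          xi <- cr$x; ti <- cr$t; mi <- cr$m
        }
        fw <- translator_forward(params, xi, config, keep_cache = TRUE,
                                 gate_u = if (config$global_gate) us[[i]] else NULL)
        resid <- (fw$pred - ti) * mi
        nm <- sum(mi)
        loss <- sum(resid^2) / nm
        if (!is.finite(loss)) {
          stop(sprintf("training diverged: non-finite loss at epoch %d", epoch), call. = FALSE)
        }
        pos <- pos + 1L
        ep_losses[pos] <- loss
        g <- translator_backward(params, config, fw$cache, 2 * resid / nm)
        gacc <- if (is.null(gacc)) g else tree_zip(gacc, g, `+`)
      }
      if (is.null(gacc)) next
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      nb <- length(batch)
      gacc <- tree_zip(gacc, gacc, function(a, b) a / nb)
      r <- adam_step(params, gacc, adam_s, lr, bc1, bc2, beta1, beta2, eps)
      params <- r$p
      adam_s <- r$s
    }
    loss_history[epoch] <- mean(ep_losses, na.rm = TRUE)
  }

  calib <- NULL
  if (config$calibration) {
    n_native <- length(config$inputs)
    FX <- do.call(rbind, lapply(seq_len(n), function(i)
      calib_stats(xs[[i]], pairs[[i]]$volumes$masks, n_native)))
    target_level <- vapply(seq_len(n), function(i) {
      cm <- pairs[[i]]$volumes$masks$gm
      if (is.null(cm) || !any(cm)) cm <- ms[[i]]
      log(max(mean(ts[[i]][cm]), 1e-8))
    }, numeric(1))
    ctr <- colMeans(FX)
    scl <- apply(FX, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-8] <- 1
    Z <- sweep(sweep(FX, 2, ctr), 2, scl, "/")
    lambda <- 0.1
    beta <- solve(crossprod(Z) + lambda * diag(ncol(Z)),
                  crossprod(Z, target_level - mean(target_level)))
    calib <- list(center = ctr, scale = scl, beta = as.vector(beta),
                  intercept = mean(target_level), lambda = lambda)
  }

  structure(list(params = params, config = config,
                 loss_history = loss_history, grid = d,
                 gate_norm = gate_norm, calibration = calib),
            class = "sabl_translator")
}

#' Predict a subject's nonspecific uptake map
#'
#' Runs the trained translator on the subject's structural MRI and returns
#' the NS estimate in SUVr units on the subject grid; negative raw outputs
#' are clamped at zero.
#'
#' @param model an `sabl_translator` from [train_translator()].
#' @param subject an `sabl_subject` (or any list providing the configured
#'   input channels plus `masks$wb`).
#' @return 3D array, the nonnegative NS estimate.
#' @export
predict_ns <- function(model, subject) {
  x <- prepare_input(subject, model$config$inputs,
                     model$config$intensity_normalization,
                     model$config$context_sigma)
  d <- dim(x)[1:3]
  if (!identical(as.integer(d), as.integer(model$grid))) {
    stop(sprintf("subject grid %s does not match model grid %s",
                 paste(d, collapse = "x"), paste(model$grid, collapse = "x")), call. = FALSE)
  }
  check_grid_levels(model$config, d)
  gu <- NULL
  if (model$config$global_gate && !is.null(model$gate_norm)) {
    gu <- (gate_stats(x) - model$gate_norm$center) / model$gate_norm$scale
  }
  pred <- translator_forward(model$params, x, model$config, gate_u = gu)$pred
  pred[pred < 0] <- 0
  if (!is.null(model$calibration)) {
    cb <- model$calibration
    z <- (calib_stats(x, subject$masks, length(model$config$inputs)) -
            cb$center) / cb$scale
    level <- exp(cb$intercept + sum(z * cb$beta))
    cm <- subject$masks$gm
    if (is.null(cm) || !any(cm)) cm <- subject$masks$wb
    factor <- level / max(mean(pred[cm]), 1e-8)
    pred <- pred * clamp(factor, 0.5, 2)
  }
  pred
}

#' Deterministic train/evaluation split
#'
#' @param indices vector of subject indices.
#' @param n_eval number of evaluation subjects (< length(indices)).
#' @param seed integer seed.
#' @return list with `train` and `eval` index vectors: disjoint, exhaustive,
#'   deterministic given `seed`.
#' @export
split_train_eval <- function(indices, n_eval, seed = 1L) {
  if (n_eval >= length(indices)) {
    stop("n_eval must be smaller than the number of indices", call. = FALSE)
  }
  if (n_eval == 0) return(list(train = indices, eval = indices[0]))
  ev <- withr::with_seed(seed, sort(sample(seq_along(indices), n_eval)))
  list(train = indices[-ev], eval = indices[ev])
}
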
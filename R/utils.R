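#' @keywords internal
#' @useDynLib sabl, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Deterministic sub-seed derivation. All stochastic operations in the package
# draw from streams seeded by values produced here, so a single top-level seed
# reproduces every artifact. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) %% 1000003) * 10007 + as.double(index) * 97 + as.double(salt) * 7919
  as.integer(s %% 2147483629)
}

stopifnot_shape <- function(a, b, what = "volumes") {
  da <- dim(a); db <- dim(b)
  if (!identical(da, db)) {
    stop(sprintf("grid mismatch for %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

# 1D Gaussian kernel matrix mapping a length-n signal to its blurred version,
# with zero (air) boundary handling.
gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  off <- (-r):r
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (m in seq_along(off)) {
    j <- seq_len(n) + off[m]
    ok <- j >= 1 & j <= n
    K[cbind(seq_len(n)[ok], j[ok])] <- K[cbind(seq_len(n)[ok], j[ok])] + k[m]
  }
  K
}

# Separable 3D Gaussian blur on a plain array; sigma in voxels, per axis.
gaussian_blur3d <- function(vol, sigma) {
  d <- dim(vol)
  stopifnot(length(d) == 3)
  sigma <- rep_len(sigma, 3L)
  if (all(sigma <= 0)) return(vol)
  x <- vol
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    K <- gauss_kernel_matrix(d[ax], sigma[ax])
    x <- aperm(x, c(ax, setdiff(1:3, ax)))
    dm <- dim(x)
    x <- K %*% matrix(x, dm[1], dm[2] * dm[3])
    dim(x) <- dm
    x <- aperm(x, order(c(ax, setdiff(1:3, ax))))
  }
  x
}

# Linear-interpolation matrix mapping nc coarse samples (at the ends and
# evenly spaced) onto nf fine positions.
interp_matrix <- function(nf, nc) {
  if (nc < 2) return(matrix(1, nf, nc))
  pos <- seq(1, nc, length.out = nf)
  lo <- pmin(floor(pos), nc - 1)
  w <- pos - lo
  M <- matrix(0, nf, nc)
  M[cbind(seq_len(nf), lo)] <- 1 - w
  M[cbind(seq_len(nf), lo + 1)] <- w
  M
}

# Smooth zero-mean random field: white noise on a coarse grid, trilinearly
# upsampled. `scale` is the approximate correlation length in voxels.
smooth_field3d <- function(dim, scale = 8, amplitude = 1, seed = NULL) {
  gen <- function() {
    nc <- pmax(2L, ceiling(dim / scale) + 1L)
    f <- array(stats::rnorm(prod(nc)), nc)
    for (ax in 1:3) {
      M <- interp_matrix(dim[ax], nc[ax])
      f <- aperm(f, c(ax, setdiff(1:3, ax)))
      dm <- dim(f)
      f <- M %*% matrix(f, dm[1], dm[2] * dm[3])
      dim(f) <- c(dim[ax], dm[2], dm[3])
      f <- aperm(f, order(c(ax, setdiff(1:3, ax))))
    }
    f <- f - mean(f)
    s <- stats::sd(f)
    if (s > 0) f <- f / s
    f * amplitude
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Binary erosion with the 6-connected (face-neighbour) structuring element.
erode3d <- function(mask, iterations = 1L) {
  stopifnot(length(dim(mask)) == 3)
  m <- mask
  d <- dim(m)
  for (it in seq_len(iterations)) {
    out <- m
    z <- array(FALSE, d)
    shift <- function(arr, ax, by) {
      res <- z
      if (by == 1) {
        idx_to <- 2:d[ax]; idx_from <- 1:(d[ax] - 1)
      } else {
        idx_to <- 1:(d[ax] - 1); idx_from <- 2:d[ax]
      }
      if (ax == 1) res[idx_to, , ] <- arr[idx_from, , ]
      if (ax == 2) res[, idx_to, ] <- arr[, idx_from, ]
      if (ax == 3) res[, , idx_to] <- arr[, , idx_from]
      res
    }
    for (ax in 1:3) for (by in c(1, -1)) out <- out & shift(m, ax, by)
    m <- out
  }
  m
}

# Linear voxel indices inside a sphere (center/radius in voxel units),
# restricted to the grid.
sphere_indices <- function(dim, center, radius) {
  lo <- pmax(1L, floor(center - radius))
  hi <- pmin(dim, ceiling(center + radius))
  if (any(lo > hi)) return(integer(0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  keep <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  g$x + dim[1] * (g$y - 1L) + dim[1] * dim[2] * (g$z - 1L)
}

# Per-volume z-scoring inside a mask; voxels outside the mask are set to zero.
zscore_in_mask <- function(vol, mask) {
  v <- vol[mask]
  mu <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) s <- 1
  out <- array(0, dim(vol))
  out[mask] <- (v - mu) / s
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
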
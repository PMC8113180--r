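## R-side wrappers for the compiled 3D convolution kernels (src/conv3d.cpp)
## plus pooling/upsampling primitives. Convolutions are 3x3x3, stride 1,
## zero padding 1; weights for a layer with Cin input and Cout output
## channels form a (27*Cin) x Cout matrix with offset-fastest row order.
## Correctness is pinned by a brute-force direct-convolution oracle and
## numerical gradient checks in the test suite.

# x: 4D array (d1, d2, d3, Cin). Returns an nvox x Cout matrix.
conv3d_forward <- function(x, W, b) {
  d <- dim(x)
  conv3d_forward_cpp(as.double(x), as.integer(d[1:3]), as.integer(d[4]), W, as.double(b))
}

# dy: nvox x Cout matrix of output-side gradients; x the layer input that
# produced them. Returns dW, db and (unless the layer is the first) dx as a
# 4D array on the input grid.
conv3d_backward <- function(dy, x, W, need_dx = TRUE) {
  d <- dim(x)
  out <- conv3d_backward_cpp(as.double(x), as.integer(d[1:3]), as.integer(d[4]),
                             dy, W, need_dx)
  res <- list(dW = out$dW, db = as.double(out$db))
  if (need_dx) {
    dx <- out$dx
    dim(dx) <- d
    res$dx <- dx
  }
  res
}

# Factor-2 average pooling (dims must be even) and the adjoints of pooling
# and nearest-neighbour upsampling, used by the multi-scale branches.
pool_avg2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1, d[1], 2); o2 <- seq(1, d[2], 2); o3 <- seq(1, d[3], 2)
  y <- x[o1, , , , drop = FALSE] + x[o1 + 1, , , , drop = FALSE]
  y <- y[, o2, , , drop = FALSE] + y[, o2 + 1, , , drop = FALSE]
  y <- y[, , o3, , drop = FALSE] + y[, , o3 + 1, , drop = FALSE]
  y / 8
}

upsample_nearest2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

upsample_nearest2_adj <- function(g) pool_avg2(g) * 8
pool_avg2_adj <- function(g) upsample_nearest2(g) / 8
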
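# Neural-network layer helpers on top of the autodiff core.
#
# Feature maps are stored as (N*H*W) x C matrices in row order
# r = (i-1)*H*W + (y-1)*W + x  (x fastest, then y, then image i), so a 2-D
# convolution is an index gather (im2col) followed by one BLAS matmul.

# Glorot-uniform initialiser; draws from the current RNG stream
nn_init <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- batch normalization ----------------------------------------------------

bn_new <- function(C) {
  list(gamma = matrix(1, 1L, C), beta = matrix(0, 1L, C))
}

bn_state_new <- function(C) {
  list(mean = matrix(0, 1L, C), var = matrix(1, 1L, C))
}

# X: node (rows x C). gamma/beta: parameter nodes (1 x C). run: plain running
# stats, updated as a side effect when training. Returns list(out, run).
bn_forward <- function(X, gamma, beta, run, training,
                       momentum = 0.1, eps = 1e-5) {
  if (training) {
    out <- ad_batchnorm(X, gamma, beta, eps)
    run$mean <- (1 - momentum) * run$mean + momentum * out$batch_mean
    run$var <- (1 - momentum) * run$var + momentum * out$batch_var
  } else {
    xc <- ad_add_rowvec(X, ad_const(-run$mean))
    inv <- 1 / sqrt(run$var + eps)
    xhat <- ad_mul_rowvec(xc, ad_const(inv))
    out <- ad_add_rowvec(ad_mul_rowvec(xhat, gamma), beta)
  }
  list(out = out, run = run)
}

# ---- group normalization (one group = the whole sub-map, per image) ---------

gn_forward <- function(X, group, N, HW, gamma, beta, eps = 1e-5) {
  C <- ncol(X$value)
  denom <- HW * C
  tot <- ad_rowsums(ad_rowsum_groups(X, group, N))
  m <- ad_scale_const(tot, 1 / denom)
  xc <- ad_add_colvec(X, ad_scale_const(ad_gather_rows(m, group), -1))
  vtot <- ad_rowsums(ad_rowsum_groups(ad_square(xc), group, N))
  v <- ad_scale_const(vtot, 1 / denom)
  inv <- ad_reciprocal(ad_sqrt_eps(v, eps))
  xhat <- ad_mul_colvec(xc, ad_gather_rows(inv, group))
  ad_add_rowvec(ad_mul_rowvec(xhat, gamma), beta)
}

# ---- 2-D convolution via im2col ---------------------------------------------

# Precompute gather indices for a k x k convolution with given stride and
# zero padding. Returns source-row indices (0 = padding) of shape
# (N*Ho*Wo) x (k*k), plus output spatial dims.
im2col_idx <- function(N, H, W, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  yo <- rep(seq_len(Ho), each = Wo)
  xo <- rep(seq_len(Wo), times = Ho)
  R1 <- Ho * Wo
  idx1 <- matrix(0L, R1, k * k)
  j <- 0L
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      j <- j + 1L
      y <- (yo - 1L) * stride + dy - pad
      x <- (xo - 1L) * stride + dx - pad
      ok <- y >= 1L & y <= H & x >= 1L & x <= W
      idx1[ok, j] <- (y[ok] - 1L) * W + x[ok]
    }
  }
  # replicate per image with row offsets
  offs <- (seq_len(N) - 1L) * H * W
  idx <- matrix(0L, N * R1, k * k)
  for (i in seq_len(N)) {
    block <- idx1
    nz <- block != 0L
    block[nz] <- block[nz] + offs[i]
    idx[(i - 1L) * R1 + seq_len(R1), ] <- block
  }
  list(idx = idx, Ho = Ho, Wo = Wo, k = k, N = N, HWout = Ho * Wo)
}

conv_w_init <- function(k, Cin, Cout) {
  nn_init(k * k * Cin, Cout, fan_in = k * k * Cin, fan_out = Cout)
}

# X: node (N*H*W) x Cin; Wn: ((k*k*Cin) x Cout) with row index j + (c-1)*k*k;
# bn_: 1 x Cout bias node or NULL. Returns node (N*Ho*Wo) x Cout.
conv2d_forward <- function(X, idxinfo, Wn, bn_) {
  ad_conv2d(X, Wn, bn_, idxinfo)
}

# global average pooling over spatial positions: (N*H*W) x C -> N x C
gap_forward <- function(X, group, N, HW) {
  ad_scale_const(ad_rowsum_groups(X, group, N), 1 / HW)
}

# row-group vector (image id per row) for an N x H x W layout
row_group <- function(N, HW) rep(seq_len(N), each = HW)

# ---- 1-D convolution (kernel 3, padding 1, single channel) ------------------

# X: node n x F; w: 1 x 3 parameter node; b: 1 x 1 parameter node
conv1d3_forward <- function(X, w, b) {
  n <- nrow(X$value)
  F <- ncol(X$value)
  z <- ad_const(matrix(0, n, 1L))
  Xp <- ad_cbind_list(list(z, X, z))
  out <- ad_add(
    ad_add(ad_mul_scalar(ad_gather_cols(Xp, seq_len(F)), ad_gather_cols(w, 1L)),
           ad_mul_scalar(ad_gather_cols(Xp, seq_len(F) + 1L), ad_gather_cols(w, 2L))),
    ad_mul_scalar(ad_gather_cols(Xp, seq_len(F) + 2L), ad_gather_cols(w, 3L)))
  ad_add_scalar(out, b)
}

# linear layer: X (n x p) %*% W (p x q) + b (1 x q)
linear_forward <- function(X, W, b) {
  ad_add_rowvec(ad_matmul(X, W), b)
}
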
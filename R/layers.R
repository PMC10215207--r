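# Internal layer primitives with explicit forward/backward passes.
# Tensors are (C, D, H, W) arrays; batch size is implicitly 1.
# Convolution and resampling kernels live in src/ops.cpp; batch
# normalization and pointwise ops are vectorized R.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

as_cmat <- function(x) matrix(x, nrow = dim(x)[1])

# With batch size 1 the per-channel statistics are taken over the
# spatial volume, i.e. batch normalization degenerates to instance
# normalization.  The current volume's statistics are therefore used in
# BOTH training and inference (running averages are still tracked for
# the record): with one-volume batches, frozen running statistics would
# reintroduce a train/inference distribution mismatch for no benefit.
bn_forward <- function(x, gamma, beta, buf, training) {
  d <- dim(x)
  m <- as_cmat(x)
  mu <- rowMeans(m)
  va <- rowMeans(m * m) - mu * mu
  if (training) {
    buf$rm <- (1 - BN_MOMENTUM) * buf$rm + BN_MOMENTUM * mu
    buf$rv <- (1 - BN_MOMENTUM) * buf$rv + BN_MOMENTUM * va
  }
  istd <- 1 / sqrt(va + BN_EPS)
  xhat <- (m - mu) * istd
  y <- array(gamma * xhat + beta, dim = d)
  list(y = y, cache = if (training) list(xhat = xhat, istd = istd) else NULL,
       buf = buf)
}

bn_backward <- function(gy, gamma, cache) {
  d <- dim(gy)
  gm <- as_cmat(gy)
  xhat <- cache$xhat
  dgamma <- rowSums(gm * xhat)
  dbeta <- rowSums(gm)
  dxhat <- gm * gamma
  gx <- cache$istd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(gx = array(gx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

# conv -> BN -> ReLU, twice ("double convolution" unit)
block_forward <- function(x, p, buf, training) {
  z1 <- cpp_conv3d_fwd(x, p$w1, p$b1, 3L)
  bn1 <- bn_forward(z1, p$g1, p$be1, buf$bn1, training)
  a1 <- relu_forward(bn1$y)
  z2 <- cpp_conv3d_fwd(a1, p$w2, p$b2, 3L)
  bn2 <- bn_forward(z2, p$g2, p$be2, buf$bn2, training)
  y <- relu_forward(bn2$y)
  buf$bn1 <- bn1$buf
  buf$bn2 <- bn2$buf
  cache <- if (training) {
    list(x = x, bn1 = bn1$cache, bn1y = bn1$y, a1 = a1,
         bn2 = bn2$cache, bn2y = bn2$y)
  } else NULL
  list(y = y, cache = cache, buf = buf)
}

block_backward <- function(gy, p, cache) {
  gy <- gy * (cache$bn2y > 0)
  bb2 <- bn_backward(gy, p$g2, cache$bn2)
  cv2 <- cpp_conv3d_bwd(cache$a1, p$w2, bb2$gx, 3L)
  ga1 <- cv2$gx * (cache$bn1y > 0)
  bb1 <- bn_backward(ga1, p$g1, cache$bn1)
  cv1 <- cpp_conv3d_bwd(cache$x, p$w1, bb1$gx, 3L)
  list(gx = cv1$gx,
       grads = list(w1 = cv1$gw, b1 = cv1$gb, g1 = bb1$dgamma, be1 = bb1$dbeta,
                    w2 = cv2$gw, b2 = cv2$gb, g2 = bb2$dgamma, be2 = bb2$dbeta))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

init_conv <- function(cin, cout, k) {
  kk <- cin * k^3
  list(w = matrix(rnorm(cout * kk, sd = sqrt(2 / kk)), nrow = cout),
       b = rep(0, cout))
}

init_block_params <- function(cin, cout) {
  c1 <- init_conv(cin, cout, 3L)
  c2 <- init_conv(cout, cout, 3L)
  list(w1 = c1$w, b1 = c1$b, g1 = rep(1, cout), be1 = rep(0, cout),
       w2 = c2$w, b2 = c2$b, g2 = rep(1, cout), be2 = rep(0, cout))
}

init_block_buffers <- function(cout) {
  list(bn1 = list(rm = rep(0, cout), rv = rep(1, cout)),
       bn2 = list(rm = rep(0, cout), rv = rep(1, cout)))
}

block_param_count <- function(cin, cout) {
  (27 * cin + 1) * cout + (27 * cout + 1) * cout + 4 * cout
}
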
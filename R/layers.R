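# Low-level tensor operations for the CNN stack.
#
# Activations are dense arrays in channels-last layout, dim c(N, H, W, C),
# or plain N x d matrices for vector stages. Convolutions are computed by
# im2col + BLAS matrix multiply; every operation has a matching backward
# pass so the reduced-scale builders can be trained by backpropagation.
# Convolutions and pooling use half padding (floor(k/2)) so stride-1 stages
# preserve spatial size and stride-2 stages halve it (rounding up).

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xp[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  xp
}

conv_out_len <- function(len, k, stride, pad) (len + 2L * pad - k) %/% stride + 1L

# patches matrix (N*OH*OW) x (k*k*C); column order ky-fastest, then kx,
# then channel, matching R's column-major flattening of a (k,k,Cin,Cout)
# weight array.
im2col <- function(x, k, stride, pad) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  xp <- pad_hw(x, pad)
  OH <- conv_out_len(H, k, stride, pad)
  OW <- conv_out_len(W, k, stride, pad)
  ys <- seq(1L, by = stride, length.out = OH)
  xs <- seq(1L, by = stride, length.out = OW)
  P <- matrix(0, N * OH * OW, k * k * C)
  col <- 0L
  for (c in seq_len(C)) for (kx in seq_len(k)) for (ky in seq_len(k)) {
    col <- col + 1L
    P[, col] <- xp[, ys + ky - 1L, xs + kx - 1L, c]
  }
  list(P = P, OH = OH, OW = OW)
}

col2im <- function(dP, dimx, k, stride, pad, OH, OW) {
  N <- dimx[1]; H <- dimx[2]; W <- dimx[3]; C <- dimx[4]
  dxp <- array(0, c(N, H + 2L * pad, W + 2L * pad, C))
  ys <- seq(1L, by = stride, length.out = OH)
  xs <- seq(1L, by = stride, length.out = OW)
  col <- 0L
  for (c in seq_len(C)) for (kx in seq_len(k)) for (ky in seq_len(k)) {
    col <- col + 1L
    dxp[, ys + ky - 1L, xs + kx - 1L, c] <-
      dxp[, ys + ky - 1L, xs + kx - 1L, c] + array(dP[, col], c(N, OH, OW))
  }
  if (pad > 0L) dxp[, pad + seq_len(H), pad + seq_len(W), , drop = FALSE] else dxp
}

conv_fwd <- function(x, Wt, b, stride, cache = FALSE) {
  k <- dim(Wt)[1]; Cout <- dim(Wt)[4]
  pad <- k %/% 2L
  ic <- im2col(x, k, stride, pad)
  Wm <- matrix(Wt, ncol = Cout)
  out_m <- ic$P %*% Wm
  out_m <- sweep(out_m, 2L, b, "+")
  out <- array(out_m, c(dim(x)[1], ic$OH, ic$OW, Cout))
  if (cache) attr(out, "cache") <- list(P = ic$P, dimx = dim(x), k = k,
                                        stride = stride, pad = pad,
                                        OH = ic$OH, OW = ic$OW)
  out
}

conv_bwd <- function(dout, Wt, cache) {
  Cout <- dim(Wt)[4]
  dm <- matrix(dout, ncol = Cout)
  Wm <- matrix(Wt, ncol = Cout)
  dW <- array(crossprod(cache$P, dm), dim(Wt))
  db <- colSums(dm)
  dP <- dm %*% t(Wm)
  dx <- col2im(dP, cache$dimx, cache$k, cache$stride, cache$pad,
               cache$OH, cache$OW)
  list(dx = dx, dW = dW, db = db)
}

# channel-wise (depthwise) grouped convolution: one k x k filter per channel
dwconv_fwd <- function(x, Wt, b, stride, cache = FALSE) {
  d <- dim(x); N <- d[1]; C <- d[4]
  k <- dim(Wt)[1]
  pad <- k %/% 2L
  xp <- pad_hw(x, pad)
  OH <- conv_out_len(d[2], k, stride, pad)
  OW <- conv_out_len(d[3], k, stride, pad)
  ys <- seq(1L, by = stride, length.out = OH)
  xs <- seq(1L, by = stride, length.out = OW)
  out <- array(rep(b, each = N * OH * OW), c(N, OH, OW, C))
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    sl <- xp[, ys + ky - 1L, xs + kx - 1L, , drop = FALSE]
    out <- out + sl * rep(Wt[ky, kx, ], each = N * OH * OW)
  }
  if (cache) attr(out, "cache") <- list(xp = xp, dimx = d, k = k,
                                        stride = stride, pad = pad,
                                        OH = OH, OW = OW)
  out
}

dwconv_bwd <- function(dout, Wt, cache) {
  N <- cache$dimx[1]; C <- cache$dimx[4]
  k <- cache$k; OH <- cache$OH; OW <- cache$OW
  ys <- seq(1L, by = cache$stride, length.out = OH)
  xs <- seq(1L, by = cache$stride, length.out = OW)
  dxp <- array(0, dim(cache$xp))
  dW <- array(0, dim(Wt))
  m <- N * OH * OW
  dm <- matrix(dout, m, C)
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    sl <- cache$xp[, ys + ky - 1L, xs + kx - 1L, , drop = FALSE]
    dW[ky, kx, ] <- colSums(matrix(sl, m, C) * dm)
    dxp[, ys + ky - 1L, xs + kx - 1L, ] <-
      dxp[, ys + ky - 1L, xs + kx - 1L, , drop = FALSE] +
      dout * rep(Wt[ky, kx, ], each = m)
  }
  p <- cache$pad
  dx <- if (p > 0L)
    dxp[, p + seq_len(cache$dimx[2]), p + seq_len(cache$dimx[3]), ,
        drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = colSums(dm))
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dout, x) dout * (x > 0)

# batch normalization over channels (last dim); works for 4-D activations
# and N x d matrices alike by reshaping to (m, C)
bn_reshape <- function(x) {
  d <- dim(x)
  C <- d[length(d)]
  matrix(x, ncol = C)
}

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  xm <- bn_reshape(x)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- sweep(xm, 2L, mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  ym <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  y <- array(ym, d)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dout, gamma, cache) {
  dm <- matrix(dout, ncol = length(gamma))
  m <- nrow(dm)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2L, gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
  dx <- array(sweep(t1 - t2, 2L, cache$invstd, "*"), cache$d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool_fwd <- function(x, k, stride, cache = FALSE) {
  d <- dim(x); N <- d[1]; C <- d[4]
  pad <- k %/% 2L
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite activations reached max pooling", call. = FALSE)
  xp <- pad_hw(x, pad) # zero padding competes in the max; inputs follow ReLU so are >= 0
  OH <- conv_out_len(d[2], k, stride, pad)
  OW <- conv_out_len(d[3], k, stride, pad)
  ys <- seq(1L, by = stride, length.out = OH)
  xs <- seq(1L, by = stride, length.out = OW)
  out <- array(-Inf, c(N, OH, OW, C))
  off <- array(1L, c(N, OH, OW, C))
  o <- 0L
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    o <- o + 1L
    sl <- xp[, ys + ky - 1L, xs + kx - 1L, , drop = FALSE]
    upd <- sl > out
    out[upd] <- sl[upd]
    off[upd] <- o
  }
  if (cache) attr(out, "cache") <- list(dimx = d, k = k, stride = stride,
                                        pad = pad, OH = OH, OW = OW,
                                        off = off, dimxp = dim(xp))
  out
}

maxpool_bwd <- function(dout, cache) {
  k <- cache$k
  ys <- seq(1L, by = cache$stride, length.out = cache$OH)
  xs <- seq(1L, by = cache$stride, length.out = cache$OW)
  dxp <- array(0, cache$dimxp)
  o <- 0L
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    o <- o + 1L
    contrib <- dout * (cache$off == o)
    dxp[, ys + ky - 1L, xs + kx - 1L, ] <-
      dxp[, ys + ky - 1L, xs + kx - 1L, , drop = FALSE] + contrib
  }
  p <- cache$pad
  if (p > 0L)
    dxp[, p + seq_len(cache$dimx[2]), p + seq_len(cache$dimx[3]), ,
        drop = FALSE]
  else dxp
}

gap_fwd <- function(x) {
  d <- dim(x)
  xr <- x
  dim(xr) <- c(d[1], d[2] * d[3], d[4])
  apply(xr, c(1, 3), mean)
}

gap_bwd <- function(dout, dimx) {
  N <- dimx[1]; H <- dimx[2]; W <- dimx[3]; C <- dimx[4]
  g <- dout / (H * W)
  dx <- array(0, dimx)
  for (c in seq_len(C)) dx[, , , c] <- array(rep(g[, c], H * W), c(N, H, W))
  dx
}

flatten_fwd <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(x, d[1], prod(d[-1]))
}

fc_fwd <- function(x, Wt, b) sweep(x %*% Wt, 2L, b, "+")
fc_bwd <- function(dout, x, Wt)
  list(dx = dout %*% t(Wt), dW = crossprod(x, dout), db = colSums(dout))

# Single-head scaled dot-product self-attention over the flattened pooled
# vector (one token per sample). Query/key/value project d -> dk and the
# output projection restores width d. With a single token the attention
# weight is identically 1, so queries and keys shape the layer's capacity
# and parameter count but receive zero gradient in this configuration.
attention_fwd <- function(x, p) {
  v <- sweep(x %*% p$Wv, 2L, p$bv, "+")
  sweep(v %*% p$Wo, 2L, p$bo, "+")
}

attention_bwd <- function(dout, x, p) {
  v <- sweep(x %*% p$Wv, 2L, p$bv, "+")
  dWo <- crossprod(v, dout)
  dbo <- colSums(dout)
  dv <- dout %*% t(p$Wo)
  dWv <- crossprod(x, dv)
  dbv <- colSums(dv)
  dx <- dv %*% t(p$Wv)
  list(dx = dx, dWv = dWv, dbv = dbv, dWo = dWo, dbo = dbo,
       dWq = p$Wq * 0, dbq = p$bq * 0, dWk = p$Wk * 0, dbk = p$bk * 0)
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}
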
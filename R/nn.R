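# Compact CPU network engine: im2col convolutions via BLAS matrix products,
# explicit forward/backward per layer, SGD with momentum. Activations are
# arrays of shape (H, W, C, N).

# ---- im2col machinery -------------------------------------------------------

# Index matrix (K^2*C x Ho*Wo) into a zero-padded (Hp, Wp, C) volume.
# Row order: kernel row fastest, then kernel col, then channel -- the same
# order conv weight matrices use.
im2col_index <- function(h, w, c, k, stride, pad) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  kern <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * hp, "+"))
  patch <- as.vector(outer(kern, (0:(c - 1L)) * hp * wp, "+"))
  pos <- as.vector(outer((0:(ho - 1L)) * stride, (0:(wo - 1L)) * stride * hp, "+"))
  idx <- outer(patch, pos, "+") + 1L
  list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp)
}

pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# Patch matrix (K^2*C x Ho*Wo*N) for a batch.
im2col <- function(x, ii, pad) {
  d <- dim(x)
  xp <- pad_input(x, pad)
  dim(xp) <- c(ii$hp * ii$wp * d[3], d[4])
  p <- xp[as.vector(ii$idx), , drop = FALSE]
  dim(p) <- c(nrow(ii$idx), ncol(ii$idx) * d[4])
  p
}

# Scatter-add of a patch-gradient matrix back to input shape.
col2im <- function(dp, ii, h, w, c, n, pad) {
  dim(dp) <- c(nrow(ii$idx) * ncol(ii$idx), n)
  groups <- rep(as.vector(ii$idx), times = 1L)
  agg <- rowsum(dp, group = groups)
  dxp <- matrix(0, ii$hp * ii$wp * c, n)
  dxp[as.integer(rownames(agg)), ] <- agg
  dim(dxp) <- c(ii$hp, ii$wp, c, n)
  dxp[pad + seq_len(h), pad + seq_len(w), , , drop = FALSE]
}

# ---- convolution ------------------------------------------------------------

conv_forward <- function(x, weight, spec) {
  d <- dim(x)
  pad <- (spec$k - 1L) %/% 2L
  ii <- im2col_index(d[1], d[2], spec$c_in, spec$k, spec$stride, pad)
  p <- im2col(x, ii, pad)
  npos <- ii$ho * ii$wo * d[4]
  if (!spec$depthwise) {
    y <- weight %*% p                       # (C_out x K^2*C_in) x (... x npos)
  } else {
    k2 <- spec$k^2
    dim(p) <- c(k2, spec$c_in, npos)
    y <- matrix(0, spec$c_out, npos)
    for (ch in seq_len(spec$c_in)) {
      y[ch, ] <- weight[ch, , drop = FALSE] %*% p[, ch, ]
    }
    dim(p) <- c(k2 * spec$c_in, npos)
  }
  dim(y) <- c(spec$c_out, ii$ho, ii$wo, d[4])
  out <- aperm(y, c(2, 3, 1, 4))
  list(out = out, cache = list(p = p, ii = ii, in_dim = d, pad = pad, spec = spec))
}

conv_backward <- function(dout, weight, cache) {
  sp <- cache$spec
  d <- cache$in_dim
  n <- d[4]
  dy <- aperm(dout, c(3, 1, 2, 4))
  dim(dy) <- c(sp$c_out, cache$ii$ho * cache$ii$wo * n)
  if (!sp$depthwise) {
    dw <- dy %*% t(cache$p)
    dp <- crossprod(weight, dy)
  } else {
    k2 <- sp$k^2
    npos <- ncol(dy)
    p3 <- cache$p
    dim(p3) <- c(k2, sp$c_in, npos)
    dw <- matrix(0, sp$c_in, k2)
    dp <- array(0, dim = c(k2, sp$c_in, npos))
    for (ch in seq_len(sp$c_in)) {
      dw[ch, ] <- dy[ch, , drop = FALSE] %*% t(p3[, ch, ])
      dp[, ch, ] <- crossprod(weight[ch, , drop = FALSE], dy[ch, , drop = FALSE])
    }
    dim(dp) <- c(k2 * sp$c_in, npos)
  }
  dx <- col2im(dp, cache$ii, d[1], d[2], sp$c_in, n, cache$pad)
  list(dx = dx, dw = dw)
}

# ---- batch normalization ----------------------------------------------------

bn_forward <- function(x, gamma, beta, state, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    m <- nrow(xm)
    unbias <- if (m > 1) m / (m - 1) else 1
    state$var <- (1 - momentum) * state$var + momentum * v * unbias
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = nrow(xm))) * rep(invstd, each = nrow(xm))
  ym <- xhat * rep(gamma, each = nrow(xm)) + rep(beta, each = nrow(xm))
  dim(ym) <- c(d[1], d[2], d[4], d[3])
  out <- aperm(ym, c(1, 2, 4, 3))
  list(out = out, state = state,
       cache = list(xhat = xhat, invstd = invstd, d = d))
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$d
  dym <- aperm(dout, c(1, 2, 4, 3))
  dim(dym) <- c(d[1] * d[2] * d[4], d[3])
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  t1 <- dym - rep(dbeta / m, each = m) -
    cache$xhat * rep(dgamma / m, each = m)
  dxm <- t1 * rep(gamma * cache$invstd, each = m)
  dim(dxm) <- c(d[1], d[2], d[4], d[3])
  dx <- aperm(dxm, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- pooling ----------------------------------------------------------------

maxpool_forward <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  hp <- d[1] + 2L * pad; wp <- d[2] + 2L * pad
  xp <- array(-Inf, dim = c(hp, wp, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  ii <- im2col_index(d[1], d[2], 1L, k, stride, pad)
  cn <- d[3] * d[4]
  dim(xp) <- c(hp * wp, cn)
  p <- xp[as.vector(ii$idx), , drop = FALSE]
  npos <- ii$ho * ii$wo
  dim(p) <- c(k * k, npos, cn)
  val <- matrix(p[1, , ], npos, cn)
  arg <- matrix(1L, npos, cn)
  for (q in 2:(k * k)) {
    pq <- matrix(p[q, , ], npos, cn)
    better <- pq > val
    val[better] <- pq[better]
    arg[better] <- q
  }
  out <- val
  dim(out) <- c(ii$ho, ii$wo, d[3], d[4])
  list(out = out, cache = list(arg = arg, ii = ii, d = d, hp = hp, wp = wp,
                               pad = pad))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$d
  ii <- cache$ii
  npos <- ii$ho * ii$wo
  cn <- d[3] * d[4]
  idx_vec <- as.vector(ii$idx)           # (k2 * npos)
  k2 <- nrow(ii$idx)
  lin <- as.vector(cache$arg) + k2 * rep(0:(npos - 1L), times = cn)
  win <- idx_vec[lin]                    # plane index of each winner
  cnrep <- rep(seq_len(cn) - 1L, each = npos)
  fi <- win + cnrep * (cache$hp * cache$wp)
  dv <- as.vector(dout)
  agg <- rowsum(dv, group = fi)
  dxp <- numeric(cache$hp * cache$wp * cn)
  dxp[as.integer(rownames(agg))] <- agg
  dim(dxp) <- c(cache$hp, cache$wp, d[3], d[4])
  dxp[cache$pad + seq_len(d[1]), cache$pad + seq_len(d[2]), , , drop = FALSE]
}

gap_forward <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  out <- matrix(colMeans(xm), d[3], d[4])
  list(out = out, cache = d)
}

gap_backward <- function(dout, d) {
  g <- rep(as.vector(dout) / (d[1] * d[2]), each = d[1] * d[2])
  array(g, dim = d)
}

# ---- squeeze-and-excitation -------------------------------------------------

se_forward <- function(x, se) {
  d <- dim(x)
  g0 <- gap_forward(x)
  s <- g0$out                               # C x N
  z1 <- se$w1 %*% s + se$b1
  a1 <- pmax(z1, 0)
  z2 <- se$w2 %*% a1 + se$b2
  g <- sigmoid(z2)                          # C x N gates in (0,1)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  ym <- xm * rep(as.vector(g), each = d[1] * d[2])
  dim(ym) <- d
  list(out = ym, cache = list(x = x, s = s, z1 = z1, a1 = a1, g = g, d = d))
}

se_backward <- function(dout, se, cache) {
  d <- cache$d
  hw <- d[1] * d[2]
  dym <- dout; dim(dym) <- c(hw, d[3] * d[4])
  xm <- cache$x; dim(xm) <- c(hw, d[3] * d[4])
  gvec <- as.vector(cache$g)
  dxm <- dym * rep(gvec, each = hw)
  dg <- matrix(colSums(dym * xm), d[3], d[4])
  dz2 <- dg * cache$g * (1 - cache$g)
  dw2 <- dz2 %*% t(cache$a1)
  db2 <- rowSums(dz2)
  da1 <- crossprod(se$w2, dz2)
  dz1 <- da1 * (cache$z1 > 0)
  dw1 <- dz1 %*% t(cache$s)
  db1 <- rowSums(dz1)
  ds <- crossprod(se$w1, dz1)               # C x N
  dxm <- dxm + rep(as.vector(ds) / hw, each = hw)
  dim(dxm) <- d
  list(dx = dxm, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

# ---- residual block ---------------------------------------------------------

block_forward <- function(x, bp, bstate, bs, train) {
  act <- get_activation(bs$activation)
  inner_ok <- bs$nested && bs$conv1$stride == 1L && bs$conv1$c_in == bs$conv1$c_out
  c1 <- conv_forward(x, bp$conv1, bs$conv1)
  b1 <- bn_forward(c1$out, bp$bn1$gamma, bp$bn1$beta, bstate$bn1, train)
  a1 <- act$f(b1$out)
  u <- if (inner_ok) a1 + x else a1
  c2 <- conv_forward(u, bp$conv2, bs$conv2)
  b2 <- bn_forward(c2$out, bp$bn2$gamma, bp$bn2$beta, bstate$bn2, train)
  h2 <- b2$out
  se_c <- NULL
  if (bs$use_se) {
    sef <- se_forward(h2, bp$se)
    h2 <- sef$out
    se_c <- sef$cache
  }
  if (!is.null(bp$proj)) {
    pc <- conv_forward(x, bp$proj, bs$projection)
    pb <- bn_forward(pc$out, bp$proj_bn$gamma, bp$proj_bn$beta,
                     bstate$proj_bn, train)
    short <- pb$out
  } else {
    pc <- pb <- NULL
    short <- x
  }
  pre <- h2 + short
  out <- act$f(pre)
  bstate$bn1 <- b1$state; bstate$bn2 <- b2$state
  if (!is.null(pb)) bstate$proj_bn <- pb$state
  list(out = out, state = bstate,
       cache = list(c1 = c1$cache, b1 = b1$cache, b1out = b1$out,
                    c2 = c2$cache, b2 = b2$cache, se = se_c,
                    pc = if (!is.null(pc)) pc$cache, pb = if (!is.null(pb)) pb$cache,
                    pre = pre, inner_ok = inner_ok))
}

block_backward <- function(dout, bp, bs, cache) {
  act <- get_activation(bs$activation)
  dpre <- dout * act$grad(cache$pre)
  dh2 <- dpre
  dshort <- dpre
  g <- list()
  if (bs$use_se) {
    seb <- se_backward(dh2, bp$se, cache$se)
    dh2 <- seb$dx
    g$se <- list(w1 = seb$dw1, b1 = seb$db1, w2 = seb$dw2, b2 = seb$db2)
  }
  bb2 <- bn_backward(dh2, bp$bn2$gamma, cache$b2)
  g$bn2 <- list(gamma = bb2$dgamma, beta = bb2$dbeta)
  cb2 <- conv_backward(bb2$dx, bp$conv2, cache$c2)
  g$conv2 <- cb2$dw
  du <- cb2$dx
  da1 <- du
  dx_inner <- if (cache$inner_ok) du else 0
  db1out <- da1 * act$grad(cache$b1out)
  bb1 <- bn_backward(db1out, bp$bn1$gamma, cache$b1)
  g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  cb1 <- conv_backward(bb1$dx, bp$conv1, cache$c1)
  g$conv1 <- cb1$dw
  dx <- cb1$dx + dx_inner
  if (!is.null(bp$proj)) {
    pbb <- bn_backward(dshort, bp$proj_bn$gamma, cache$pb)
    g$proj_bn <- list(gamma = pbb$dgamma, beta = pbb$dbeta)
    pcb <- conv_backward(pbb$dx, bp$proj, cache$pc)
    g$proj <- pcb$dw
    dx <- dx + pcb$dx
  } else {
    dx <- dx + dshort
  }
  list(dx = dx, grads = g)
}
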
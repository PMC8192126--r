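# Minimal CNN engine.
#
# Layers operate on activations stored as (H*W*C) x B matrices in
# column-major (H fastest, then W, then C) layout, so each channel occupies
# a contiguous block of rows. Convolutions are strided ("same" padding with
# ceiling division), implemented by im2col gather with precomputed index
# maps; the heavy lifting is BLAS matrix multiplication. Everything needed
# for backpropagation (including gradients with respect to the input, used
# for saliency maps) is implemented here.

.EPS_BN <- 1e-3
.BN_MOMENTUM <- 0.9

# --- layer constructors -----------------------------------------------------

.layer_bn <- function(C) {
  list(type = "bn", C = C,
       gamma = rep(1, C), beta = rep(0, C),
       rmean = rep(0, C), rvar = rep(1, C))
}

.conv_plan <- function(H, W, C, kh, kw, sh, sw) {
  oh <- as.integer(ceiling(H / sh)); ow <- as.integer(ceiling(W / sw))
  ph <- max((oh - 1L) * sh + kh - H, 0L); pw <- max((ow - 1L) * sw + kw - W, 0L)
  pt <- ph %/% 2L; pl <- pw %/% 2L
  Hp <- H + ph; Wp <- W + pw
  i <- rep(seq_len(H), times = W * C)
  j <- rep(rep(seq_len(W), each = H), times = C)
  cc <- rep(seq_len(C), each = H * W)
  fill <- (i + pt) + (j + pl - 1L) * Hp + (cc - 1L) * Hp * Wp
  ki <- rep(seq_len(kh), times = kw * C)
  kj <- rep(rep(seq_len(kw), each = kh), times = C)
  kc <- rep(seq_len(C), each = kh * kw)
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  idx <- outer(ki, (oi - 1L) * sh, "+") +
    (outer(kj, (oj - 1L) * sw, "+") - 1L) * Hp +
    (kc - 1L) * Hp * Wp
  list(H = H, W = W, C = C, kh = kh, kw = kw, sh = sh, sw = sw,
       oh = oh, ow = ow, Hp = Hp, Wp = Wp,
       K = kh * kw * C, P = oh * ow,
       fill = fill, idxv = as.integer(idx))
}

.layer_conv <- function(H, W, C, filters, kernel, stride) {
  plan <- .conv_plan(H, W, C, kernel[1], kernel[2], stride[1], stride[2])
  fan_in <- plan$K
  fan_out <- kernel[1] * kernel[2] * filters
  lim <- sqrt(6 / (fan_in + fan_out))   # Glorot uniform
  W0 <- matrix(stats::runif(plan$K * filters, -lim, lim), plan$K, filters)
  list(type = "conv", plan = plan, filters = filters,
       W = W0, b = rep(0, filters))
}

.layer_lrelu <- function(slope) list(type = "lrelu", slope = slope)

.layer_dense <- function(nin) {
  lim <- sqrt(6 / (nin + 1))
  list(type = "dense", W = matrix(stats::runif(nin, -lim, lim), nin, 1),
       b = 0)
}

# reshape F x (P*B) conv output to (oh*ow*F) x B activation layout
.chw_to_hwc <- function(Z, oh, ow, nf, B) {
  a <- array(Z, c(nf, oh, ow, B))
  a <- aperm(a, c(2, 3, 1, 4))
  dim(a) <- c(oh * ow * nf, B)
  a
}
.hwc_to_chw <- function(X, oh, ow, nf, B) {
  a <- array(X, c(oh, ow, nf, B))
  a <- aperm(a, c(3, 1, 2, 4))
  dim(a) <- c(nf, oh * ow * B)
  a
}

# --- forward / backward -----------------------------------------------------

.bn_forward <- function(layer, x, train) {
  C <- layer$C
  hw <- nrow(x) / C
  B <- ncol(x)
  y <- x
  cache <- list(xhat = x, invstd = numeric(C), mu = numeric(C))
  for (c in seq_len(C)) {
    rows <- ((c - 1) * hw + 1):(c * hw)
    xc <- x[rows, , drop = FALSE]
    if (train) {
      mu <- mean(xc)
      v <- mean((xc - mu)^2)
      layer$rmean[c] <- .BN_MOMENTUM * layer$rmean[c] + (1 - .BN_MOMENTUM) * mu
      layer$rvar[c] <- .BN_MOMENTUM * layer$rvar[c] + (1 - .BN_MOMENTUM) * v
    } else {
      mu <- layer$rmean[c]
      v <- layer$rvar[c]
    }
    invstd <- 1 / sqrt(v + .EPS_BN)
    xhat <- (xc - mu) * invstd
    y[rows, ] <- layer$gamma[c] * xhat + layer$beta[c]
    cache$xhat[rows, ] <- xhat
    cache$invstd[c] <- invstd
  }
  list(layer = layer, out = y, cache = cache)
}

.bn_backward <- function(layer, dy, cache, train) {
  C <- layer$C
  hw <- nrow(dy) / C
  dx <- dy
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    rows <- ((c - 1) * hw + 1):(c * hw)
    dyc <- dy[rows, , drop = FALSE]
    xh <- cache$xhat[rows, , drop = FALSE]
    dgamma[c] <- sum(dyc * xh)
    dbeta[c] <- sum(dyc)
    if (train) {
      n <- length(dyc)
      dxhat <- dyc * layer$gamma[c]
      dx[rows, ] <- cache$invstd[c] / n *
        (n * dxhat - sum(dxhat) - xh * sum(dxhat * xh))
    } else {
      dx[rows, ] <- dyc * layer$gamma[c] * cache$invstd[c]
    }
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.conv_forward <- function(layer, x) {
  pl <- layer$plan
  B <- ncol(x)
  xp <- matrix(0, pl$Hp * pl$Wp * pl$C, B)
  xp[pl$fill, ] <- x
  A <- xp[pl$idxv, , drop = FALSE]
  dim(A) <- c(pl$K, pl$P * B)
  Z <- crossprod(layer$W, A) + layer$b
  list(out = .chw_to_hwc(Z, pl$oh, pl$ow, layer$filters, B),
       cache = list(A = A, B = B))
}

.conv_backward <- function(layer, dy, cache) {
  pl <- layer$plan
  B <- cache$B
  dZ <- .hwc_to_chw(dy, pl$oh, pl$ow, layer$filters, B)
  dW <- cache$A %*% t(dZ)
  db <- rowSums(dZ)
  dA <- layer$W %*% dZ                      # K x (P*B)
  dim(dA) <- c(pl$K * pl$P, B)
  agg <- rowsum(dA, group = pl$idxv)        # rows sorted by unique index
  dxp <- matrix(0, pl$Hp * pl$Wp * pl$C, B)
  dxp[as.integer(rownames(agg)), ] <- agg
  list(dx = dxp[pl$fill, , drop = FALSE], dW = dW, db = db)
}

.lrelu_forward <- function(layer, x) {
  neg <- x < 0
  y <- x
  y[neg] <- layer$slope * x[neg]
  list(out = y, cache = neg)
}

.lrelu_backward <- function(layer, dy, neg) {
  dx <- dy
  dx[neg] <- layer$slope * dy[neg]
  dx
}

# full forward pass; x is (H*W) x B (single input channel)
.net_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  a <- x
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "bn") {
      r <- .bn_forward(l, a, train)
      if (train) net$layers[[i]] <- r$layer   # running stats update
      caches[[i]] <- r$cache
      a <- r$out
    } else if (l$type == "conv") {
      r <- .conv_forward(l, a)
      caches[[i]] <- r$cache
      a <- r$out
    } else if (l$type == "lrelu") {
      r <- .lrelu_forward(l, a)
      caches[[i]] <- r$cache
      a <- r$out
    } else {  # dense -> logits (1 x B)
      caches[[i]] <- a
      a <- crossprod(l$W, a) + l$b
    }
  }
  list(net = net, logits = as.numeric(a), caches = caches)
}

# backward pass from dlogits; returns per-layer grads and input gradient
.net_backward <- function(net, caches, dlogits, train = TRUE) {
  grads <- vector("list", length(net$layers))
  da <- matrix(dlogits, nrow = 1)
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (l$type == "dense") {
      a_in <- caches[[i]]
      grads[[i]] <- list(dW = a_in %*% t(da), db = sum(da))
      da <- l$W %*% da
    } else if (l$type == "lrelu") {
      da <- .lrelu_backward(l, da, caches[[i]])
    } else if (l$type == "conv") {
      r <- .conv_backward(l, da, caches[[i]])
      grads[[i]] <- list(dW = r$dW, db = r$db)
      da <- r$dx
    } else {  # bn
      r <- .bn_backward(l, da, caches[[i]], train)
      grads[[i]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
      da <- r$dx
    }
  }
  list(grads = grads, dx = da)
}

# --- Adam -------------------------------------------------------------------

.adam_init <- function(net) {
  lapply(net$layers, function(l) {
    switch(l$type,
      bn = list(m = list(g = 0 * l$gamma, b = 0 * l$beta),
                v = list(g = 0 * l$gamma, b = 0 * l$beta)),
      conv = list(m = list(W = 0 * l$W, b = 0 * l$b),
                  v = list(W = 0 * l$W, b = 0 * l$b)),
      dense = list(m = list(W = 0 * l$W, b = 0),
                   v = list(W = 0 * l$W, b = 0)),
      NULL)
  })
}

.adam_step <- function(net, grads, state, step, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "lrelu") next
    g <- grads[[i]]
    s <- state[[i]]
    if (l$type == "bn") {
      u <- upd(l$gamma, g$dgamma, s$m$g, s$v$g)
      l$gamma <- u$p; s$m$g <- u$m; s$v$g <- u$v
      u <- upd(l$beta, g$dbeta, s$m$b, s$v$b)
      l$beta <- u$p; s$m$b <- u$m; s$v$b <- u$v
    } else if (l$type %in% c("conv", "dense")) {
      u <- upd(l$W, g$dW, s$m$W, s$v$W)
      l$W <- u$p; s$m$W <- u$m; s$v$W <- u$v
      u <- upd(l$b, g$db, s$m$b, s$v$b)
      l$b <- u$p; s$m$b <- u$m; s$v$b <- u$v
    }
    net$layers[[i]] <- l
    state[[i]] <- s
  }
  list(net = net, state = state)
}
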
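# Minimal neural-network compute core: dense layers, batched 2-D
# convolutions (C++ backend), residual blocks, batched fusion layers, the
# weighted binary cross-entropy, and Adam. All tensors are batch-major
# matrices: a batch of n feature maps of spatial size H x W with C channels
# is an n x (H*W*C) matrix, (h, w, c) stored column-major with the channel
# slowest. Everything here is internal; the user-facing models live in
# networks.R.

# ---- convolution geometry ---------------------------------------------

# Precompute the im2col index map for a 'same'-padded, stride-1 convolution.
# idx is 0-based; -1 marks zero padding. Patch element order: row offset
# fastest, then column offset, then input channel (the kernel matrix rows
# follow the same order).
conv_geom <- function(H, W, Cin, Fout, k = 3L) {
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  P <- H * W
  hs <- rep(seq_len(H), times = W)
  ws <- rep(seq_len(W), each = H)
  idx <- integer(P * k * k * Cin)
  j <- 0L
  for (cc in seq_len(Cin)) {
    for (dw in -r:r) {
      for (dh in -r:r) {
        h2 <- hs + dh
        w2 <- ws + dw
        ok <- h2 >= 1L & h2 <= H & w2 >= 1L & w2 <= W
        v <- rep(-1L, P)
        v[ok] <- (h2[ok] - 1L) + (w2[ok] - 1L) * H + (cc - 1L) * P
        idx[j * P + seq_len(P)] <- v
        j <- j + 1L
      }
    }
  }
  list(idx = idx, P = P, KKC = k * k * Cin, H = H, W = W,
       Cin = Cin, Fout = Fout, k = k)
}

conv_init <- function(geom) {
  list(W = matrix(stats::rnorm(geom$KKC * geom$Fout,
                               sd = sqrt(2 / geom$KKC)),
                  geom$KKC, geom$Fout),
       b = numeric(geom$Fout))
}

conv_fwd <- function(X, geom, pars) {
  nn_conv_fwd(X, geom$idx, geom$P, pars$W, pars$b)
}

conv_bwd <- function(X, geom, pars, dOut) {
  nn_conv_bwd(X, geom$idx, geom$P, pars$W, dOut)
}

# ---- dense layers ------------------------------------------------------

dense_init <- function(n_in, n_out, final = FALSE) {
  sd <- if (final) sqrt(1 / n_in) else sqrt(2 / n_in)
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
       b = numeric(n_out))
}

dense_fwd <- function(X, pars) {
  Z <- X %*% pars$W
  Z + matrix(pars$b, nrow(Z), ncol(Z), byrow = TRUE)
}

dense_bwd <- function(X, pars, dZ) {
  list(dX = dZ %*% t(pars$W),
       dW = crossprod(X, dZ),
       db = colSums(dZ))
}

relu <- function(Z) Z * (Z > 0)

# Forward through a stack of dense layers, ReLU on all, or all but the
# last when `final_linear` (the logit head).
dense_stack_fwd <- function(X, layers, final_linear = FALSE) {
  n_layers <- length(layers)
  ins <- vector("list", n_layers)
  zs <- vector("list", n_layers)
  h <- X
  for (i in seq_len(n_layers)) {
    ins[[i]] <- h
    z <- dense_fwd(h, layers[[i]])
    zs[[i]] <- z
    h <- if (final_linear && i == n_layers) z else relu(z)
  }
  list(out = h, ins = ins, zs = zs)
}

dense_stack_bwd <- function(cache, layers, dOut, final_linear = FALSE) {
  n_layers <- length(layers)
  grads <- vector("list", n_layers)
  d <- dOut
  for (i in rev(seq_len(n_layers))) {
    if (!(final_linear && i == n_layers)) d <- d * (cache$zs[[i]] > 0)
    b <- dense_bwd(cache$ins[[i]], layers[[i]], d)
    grads[[i]] <- list(W = b$dW, b = b$db)
    d <- b$dX
  }
  list(dX = d, grads = grads)
}

# ---- residual block ----------------------------------------------------

# conv -> ReLU -> ... -> conv, plus a skip connection (identity, or a 1x1
# projection when the channel count changes), ReLU after the addition.
resblock_init <- function(geoms) {
  convs <- lapply(geoms$convs, conv_init)
  proj <- if (!is.null(geoms$proj)) conv_init(geoms$proj) else NULL
  list(convs = convs, proj = proj)
}

resblock_geoms <- function(H, W, Cin, Fout, n_convs, k) {
  convs <- vector("list", n_convs)
  convs[[1]] <- conv_geom(H, W, Cin, Fout, k)
  if (n_convs > 1) {
    for (i in 2:n_convs) convs[[i]] <- conv_geom(H, W, Fout, Fout, k)
  }
  proj <- if (Cin != Fout) conv_geom(H, W, Cin, Fout, 1L) else NULL
  list(convs = convs, proj = proj)
}

resblock_fwd <- function(X, pars, geoms) {
  n_convs <- length(pars$convs)
  zs <- vector("list", n_convs)
  ins <- vector("list", n_convs)
  h <- X
  for (i in seq_len(n_convs)) {
    ins[[i]] <- h
    zs[[i]] <- conv_fwd(h, geoms$convs[[i]], pars$convs[[i]])
    if (i < n_convs) h <- relu(zs[[i]])
  }
  s <- if (is.null(pars$proj)) X else conv_fwd(X, geoms$proj, pars$proj)
  pre <- zs[[n_convs]] + s
  list(out = relu(pre), pre = pre, zs = zs, ins = ins, X = X)
}

resblock_bwd <- function(cache, pars, geoms, dOut) {
  n_convs <- length(pars$convs)
  dpre <- dOut * (cache$pre > 0)
  grads <- list(convs = vector("list", n_convs), proj = NULL)
  d <- dpre
  for (i in rev(seq_len(n_convs))) {
    if (i < n_convs) d <- d * (cache$zs[[i]] > 0)
    b <- conv_bwd(cache$ins[[i]], geoms$convs[[i]], pars$convs[[i]], d)
    grads$convs[[i]] <- list(W = b$dW, b = b$db)
    d <- b$dX
  }
  if (is.null(pars$proj)) {
    dX <- d + dpre
  } else {
    bp <- conv_bwd(cache$X, geoms$proj, pars$proj, dpre)
    grads$proj <- list(W = bp$dW, b = bp$db)
    dX <- d + bp$dX
  }
  list(dX = dX, grads = grads)
}

# ---- batched fusion layers --------------------------------------------

# Augmented outer product over a batch: rows of F1 (n x p) and F2 (n x q)
# are augmented with a 1 and multiplied pairwise. Output columns are
# ordered (i, j) with the row index i fastest, i.e. each row holds the
# (p+1) x (q+1) fused matrix in column-major order.
aug_outer_fwd <- function(F1, F2) {
  A1 <- cbind(F1, 1)
  A2 <- cbind(F2, 1)
  p1 <- ncol(A1)
  p2 <- ncol(A2)
  out <- A1[, rep(seq_len(p1), times = p2), drop = FALSE] *
    A2[, rep(seq_len(p2), each = p1), drop = FALSE]
  list(out = out, A1 = A1, A2 = A2)
}

aug_outer_bwd <- function(cache, dOut) {
  A1 <- cache$A1
  A2 <- cache$A2
  n <- nrow(A1)
  p1 <- ncol(A1)
  p2 <- ncol(A2)
  dA1 <- matrix(0, n, p1)
  dA2 <- matrix(0, n, p2)
  for (j in seq_len(p2)) {
    blk <- dOut[, (j - 1L) * p1 + seq_len(p1), drop = FALSE]
    dA1 <- dA1 + blk * A2[, j]
    dA2[, j] <- rowSums(blk * A1)
  }
  # drop the gradient of the constant augmentation column
  list(dF1 = dA1[, -p1, drop = FALSE], dF2 = dA2[, -p2, drop = FALSE])
}

# Batched multimodal circulant fusion (trainable W1, W2, W3).
mcf_batch_fwd <- function(F1, F2, pars, variant) {
  V <- F1 %*% t(pars$W1)
  C <- F2 %*% t(pars$W2)
  d <- ncol(V)
  if (variant == "matmul") {
    f <- matrix(0, nrow(V), d)
    g <- f
    for (j in seq_len(d)) {
      sh <- ((seq_len(d) - j) %% d) + 1L
      f <- f + C[, j] * V[, sh, drop = FALSE]
      g <- g + V[, j] * C[, sh, drop = FALSE]
    }
  } else {
    f <- C * (rowSums(V) / d)
    g <- V * (rowSums(C) / d)
  }
  out <- (f + g) %*% t(pars$W3)
  list(out = out, V = V, C = C, f = f, g = g)
}

mcf_batch_bwd <- function(cache, pars, variant, F1, F2, dOut) {
  V <- cache$V
  C <- cache$C
  n <- nrow(V)
  d <- ncol(V)
  dfg <- dOut %*% pars$W3
  dW3 <- crossprod(dOut, cache$f + cache$g)
  dV <- matrix(0, n, d)
  dC <- matrix(0, n, d)
  if (variant == "matmul") {
    for (j in seq_len(d)) {
      sh <- ((seq_len(d) - j) %% d) + 1L
      # f-path: f[, i] += C[, j] * V[, sh[i]]
      dV[, sh] <- dV[, sh] + dfg * C[, j]
      dC[, j] <- dC[, j] + rowSums(dfg * V[, sh, drop = FALSE])
      # g-path: g[, i] += V[, j] * C[, sh[i]]
      dC[, sh] <- dC[, sh] + dfg * V[, j]
      dV[, j] <- dV[, j] + rowSums(dfg * C[, sh, drop = FALSE])
    }
  } else {
    sv <- rowSums(V) / d
    sc <- rowSums(C) / d
    dC <- dC + dfg * sv
    dV <- dV + matrix(rowSums(dfg * C) / d, n, d)
    dV <- dV + dfg * sc
    dC <- dC + matrix(rowSums(dfg * V) / d, n, d)
  }
  list(dF1 = dV %*% pars$W1, dF2 = dC %*% pars$W2,
       grads = list(W1 = crossprod(dV, F1), W2 = crossprod(dC, F2),
                    W3 = dW3))
}

# ---- loss --------------------------------------------------------------

# Weighted binary cross-entropy from logits (numerically stable softplus
# form). Returns the mean weighted loss and the gradient w.r.t. the logits.
wbce_loss <- function(logit, y, w) {
  sp <- pmax(logit, 0) + log1p(exp(-abs(logit)))
  loss <- mean(w * (sp - y * logit))
  dlogit <- w * (stats::plogis(logit) - y) / length(y)
  list(loss = loss, dlogit = dlogit)
}

# ---- Adam --------------------------------------------------------------

# Parameters are nested lists whose leaves are numeric arrays; gradients
# mirror the structure. State holds first/second moment estimates.
nn_zeros_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) return(lapply(p, nn_zeros_like))
  p * 0
}

adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      # gradient lists may be ordered differently; match leaves by name
      keys <- names(p) %||% seq_along(p)
      out <- lapply(keys, function(i) rec(p[[i]], g[[i]], m[[i]], v[[i]]))
      list(p = stats::setNames(lapply(out, `[[`, "p"), names(p)),
           m = stats::setNames(lapply(out, `[[`, "m"), names(p)),
           v = stats::setNames(lapply(out, `[[`, "v"), names(p)))
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      p2 <- p - lr * (m2 / corr1) / (sqrt(v2 / corr2) + eps)
      list(p = p2, m = m2, v = v2)
    }
  }
  out <- rec(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}
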
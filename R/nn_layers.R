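# Internal neural-network primitives: forward passes with caches and the
# matching analytic backward passes. Everything operates on one sequence at
# a time as plain base-R matrices (rows = positions), so correctness can be
# audited against numerical gradients (see the test suite).

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# d(row-softmax): dS = P * (dP - rowSums(dP * P))
softmax_rows_backward <- function(dP, P) {
  P * (dP - rowSums(dP * P))
}

LN_EPS <- 1e-5

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  inv_sd <- 1 / sqrt(rowMeans(Xc * Xc) + LN_EPS)
  xhat <- Xc * inv_sd
  list(Y = sweep(xhat, 2L, g, "*") + matrix(b, nrow(X), length(b), byrow = TRUE),
       xhat = xhat, inv_sd = inv_sd)
}

ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

add_bias <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

init_matrix <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

# One pre-LayerNorm transformer block.
block_params_init <- function(d, d_ff) {
  list(ln1_g = rep(1, d), ln1_b = rep(0, d),
       Wq = init_matrix(d, d), bq = rep(0, d),
       Wk = init_matrix(d, d), bk = rep(0, d),
       Wv = init_matrix(d, d), bv = rep(0, d),
       Wo = init_matrix(d, d), bo = rep(0, d),
       ln2_g = rep(1, d), ln2_b = rep(0, d),
       W1 = init_matrix(d, d_ff), b1 = rep(0, d_ff),
       W2 = init_matrix(d_ff, d), b2 = rep(0, d))
}

# Distance-decay attention bias (fixed per-head slopes 2^-h): heads with
# steep slopes act locally (within-sentence context, where negation frames
# bind to their finding phrase), shallow ones keep a global view. The bias
# is a constant, so the backward pass is untouched.
alibi_bias <- function(Tn, key_idx, slope) {
  qpos <- seq_len(Tn)
  kpos <- if (is.null(key_idx)) qpos else key_idx
  -slope * abs(outer(qpos, kpos, "-"))
}

# Forward through one block. `key_idx` restricts attention keys/values to
# real (non-padding) positions; queries run at every position so padding
# rows still receive finite values without influencing real ones.
block_forward <- function(X, p, n_heads, key_idx = NULL) {
  d <- ncol(X)
  dk <- d %/% n_heads
  scale <- 1 / sqrt(dk)
  ln1 <- ln_forward(X, p$ln1_g, p$ln1_b)
  A <- ln1$Y
  Q <- add_bias(A %*% p$Wq, p$bq)
  K <- add_bias(A %*% p$Wk, p$bk)
  V <- add_bias(A %*% p$Wv, p$bv)
  Tn <- nrow(X)
  Ctx <- matrix(0, Tn, d)
  Ps <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    if (!is.null(key_idx)) {
      Kh <- Kh[key_idx, , drop = FALSE]
      Vh <- Vh[key_idx, , drop = FALSE]
    }
    S <- (Q[, cols, drop = FALSE] %*% t(Kh)) * scale +
      alibi_bias(Tn, key_idx, 2^(-h))
    P <- softmax_rows(S)
    Ps[[h]] <- P
    Ctx[, cols] <- P %*% Vh
  }
  O <- add_bias(Ctx %*% p$Wo, p$bo)
  X1 <- X + O
  ln2 <- ln_forward(X1, p$ln2_g, p$ln2_b)
  Hpre <- add_bias(ln2$Y %*% p$W1, p$b1)
  Hff <- pmax(Hpre, 0)
  Fout <- add_bias(Hff %*% p$W2, p$b2)
  X2 <- X1 + Fout
  list(X2 = X2,
       cache = list(X = X, ln1 = ln1, A = A, Q = Q, K = K, V = V, Ps = Ps,
                    Ctx = Ctx, X1 = X1, ln2 = ln2, Hff = Hff,
                    key_idx = key_idx))
}

block_backward <- function(dX2, p, cache, n_heads) {
  d <- ncol(dX2)
  dk <- d %/% n_heads
  scale <- 1 / sqrt(dk)
  g <- list()

  # FFN sub-block (residual: dX1 accumulates dX2 directly)
  dFout <- dX2
  g$b2 <- colSums(dFout)
  g$W2 <- t(cache$Hff) %*% dFout
  dHff <- (dFout %*% t(p$W2)) * (cache$Hff > 0)
  g$b1 <- colSums(dHff)
  g$W1 <- t(cache$ln2$Y) %*% dHff
  dLn2 <- dHff %*% t(p$W1)
  bb <- ln_backward(dLn2, cache$ln2, p$ln2_g)
  g$ln2_g <- bb$dg; g$ln2_b <- bb$db
  dX1 <- dX2 + bb$dX

  # Attention sub-block
  dO <- dX1
  g$bo <- colSums(dO)
  g$Wo <- t(cache$Ctx) %*% dO
  dCtx <- dO %*% t(p$Wo)
  Tn <- nrow(dX2)
  dQ <- matrix(0, Tn, d); dK <- matrix(0, Tn, d); dV <- matrix(0, Tn, d)
  ki <- cache$key_idx
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Kh <- cache$K[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    if (!is.null(ki)) {
      Kh <- Kh[ki, , drop = FALSE]
      Vh <- Vh[ki, , drop = FALSE]
    }
    P <- cache$Ps[[h]]
    dCh <- dCtx[, cols, drop = FALSE]
    dP <- dCh %*% t(Vh)
    dVh <- t(P) %*% dCh
    dS <- softmax_rows_backward(dP, P)
    dQ[, cols] <- (dS %*% Kh) * scale
    dKh <- (t(dS) %*% cache$Q[, cols, drop = FALSE]) * scale
    if (!is.null(ki)) {
      dK[ki, cols] <- dK[ki, cols] + dKh
      dV[ki, cols] <- dV[ki, cols] + dVh
    } else {
      dK[, cols] <- dKh
      dV[, cols] <- dVh
    }
  }
  A <- cache$A
  g$bq <- colSums(dQ); g$Wq <- t(A) %*% dQ
  g$bk <- colSums(dK); g$Wk <- t(A) %*% dK
  g$bv <- colSums(dV); g$Wv <- t(A) %*% dV
  dA <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  bb1 <- ln_backward(dA, cache$ln1, p$ln1_g)
  g$ln1_g <- bb1$dg; g$ln1_b <- bb1$db
  dX <- dX1 + bb1$dX
  list(dX = dX, grads = g)
}

# ---- parameter-tree arithmetic (used by the optimiser) ----

# Trees are matched by name where names exist (the two trees may list their
# fields in different orders), by position otherwise.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nm <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nm) && nzchar(nm[i])) b[[nm[i]]] else b[[i]]
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else {
    f(a)
  }
}

tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_scale <- function(a, s) tree_map(function(x) x * s, a)
tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

# Adam with bias correction; state carries first/second moment trees and the
# step counter.
adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
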
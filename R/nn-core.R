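# Minimal dense-matrix neural-network primitives with hand-derived gradients.
#
# Feature maps are stored as N x C matrices whose rows are pixel tokens in
# R's native column-major order: token t of an H x W image is pixel
# (row = (t-1) %% H + 1, col = (t-1) %/% H + 1), i.e. X[, 1] == as.vector(img).
# All backward functions return gradients exactly matching their forward
# caches; correctness is pinned by finite-difference tests.

# ---- broadcasting helpers ----------------------------------------------------

# multiply column j of X by g[j]
scale_cols <- function(X, g) X * rep(g, each = nrow(X))
# add b[j] to column j of X
add_cols <- function(X, b) X + rep(b, each = nrow(X))

# ---- parameter initialisation ------------------------------------------------

nn_rand <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

# ---- LayerNorm (per token row) -----------------------------------------------

layernorm_forward <- function(X, g, b, eps = 1e-6) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = add_cols(scale_cols(xhat, g), b),
       cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_backward <- function(dY, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- scale_cols(dY, cache$g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

# ---- activations -------------------------------------------------------------

gelu_forward <- function(X) list(out = X * stats::pnorm(X), cache = X)
gelu_backward <- function(dY, X) dY * (stats::pnorm(X) + X * stats::dnorm(X))

lrelu_forward <- function(X, alpha = 0.2) {
  list(out = ifelse(X > 0, X, alpha * X), cache = X)
}
lrelu_backward <- function(dY, X, alpha = 0.2) dY * ifelse(X > 0, 1, alpha)

# ---- window partition --------------------------------------------------------

# Tile an H x W grid into attn_window x attn_window windows; edge windows are
# truncated rather than padded, so every token belongs to exactly one window
# and no masking is needed. Returns a list of integer token-index vectors.
win_index <- function(H, W, w) {
  rb <- split(seq_len(H), ceiling(seq_len(H) / w))
  cb <- split(seq_len(W), ceiling(seq_len(W) / w))
  out <- vector("list", length(rb) * length(cb))
  k <- 1L
  for (cc in cb) {
    for (rr in rb) {
      out[[k]] <- as.integer(outer(rr, (cc - 1L) * H, "+"))
      k <- k + 1L
    }
  }
  out
}

# ---- windowed multi-head self-attention --------------------------------------

attn_forward <- function(X, Wqkv, bqkv, Wo, bo, wins, n_heads) {
  N <- nrow(X); C <- ncol(X)
  d <- C %/% n_heads
  sc <- 1 / sqrt(d)
  QKV <- add_cols(X %*% Wqkv, bqkv)
  O <- matrix(0, N, C)
  Alist <- vector("list", length(wins))
  for (wi in seq_along(wins)) {
    idx <- wins[[wi]]
    Ah <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      Q <- QKV[idx, cols, drop = FALSE]
      K <- QKV[idx, C + cols, drop = FALSE]
      V <- QKV[idx, 2L * C + cols, drop = FALSE]
      S <- tcrossprod(Q, K) * sc
      S <- S - apply(S, 1, max)
      A <- exp(S)
      A <- A / rowSums(A)
      O[idx, cols] <- A %*% V
      Ah[[h]] <- A
    }
    Alist[[wi]] <- Ah
  }
  Y <- add_cols(O %*% Wo, bo)
  list(out = Y, cache = list(X = X, QKV = QKV, O = O, Alist = Alist,
                             wins = wins, n_heads = n_heads, d = d, sc = sc))
}

attn_backward <- function(dY, cache, Wqkv, Wo) {
  X <- cache$X; QKV <- cache$QKV; O <- cache$O
  N <- nrow(X); C <- ncol(X)
  d <- cache$d; sc <- cache$sc
  dWo <- crossprod(O, dY)
  dbo <- colSums(dY)
  dO <- tcrossprod(dY, Wo)
  dQKV <- matrix(0, N, 3L * C)
  for (wi in seq_along(cache$wins)) {
    idx <- cache$wins[[wi]]
    for (h in seq_len(cache$n_heads)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      A <- cache$Alist[[wi]][[h]]
      Q <- QKV[idx, cols, drop = FALSE]
      K <- QKV[idx, C + cols, drop = FALSE]
      V <- QKV[idx, 2L * C + cols, drop = FALSE]
      dOh <- dO[idx, cols, drop = FALSE]
      dA <- tcrossprod(dOh, V)
      dV <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ <- (dS %*% K) * sc
      dK <- crossprod(dS, Q) * sc
      dQKV[idx, cols] <- dQKV[idx, cols] + dQ
      dQKV[idx, C + cols] <- dQKV[idx, C + cols] + dK
      dQKV[idx, 2L * C + cols] <- dQKV[idx, 2L * C + cols] + dV
    }
  }
  dWqkv <- crossprod(X, dQKV)
  dbqkv <- colSums(dQKV)
  dX <- tcrossprod(dQKV, Wqkv)
  list(dX = dX, dWqkv = dWqkv, dbqkv = dbqkv, dWo = dWo, dbo = dbo)
}

# ---- 2D convolution via im2col ----------------------------------------------

# Index map for a k x k convolution with stride s and zero padding p on an
# H x W grid; out-of-bounds taps point at the sentinel row N + 1 (a zero row).
conv_index <- function(H, W, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  ro <- rep(seq_len(Ho), times = Wo)
  co <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, Ho * Wo, k * k)
  j <- 1L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      r <- (ro - 1L) * stride + di - pad
      cc <- (co - 1L) * stride + dj - pad
      ok <- r >= 1L & r <= H & cc >= 1L & cc <= W
      idx[, j] <- ifelse(ok, (cc - 1L) * H + r, H * W + 1L)
      j <- j + 1L
    }
  }
  list(idx = idx, Ho = Ho, Wo = Wo, k = k, N = H * W)
}

conv_forward <- function(X, W, b, ci) {
  Cin <- ncol(X)
  Xa <- rbind(X, 0)
  kk <- ncol(ci$idx)
  Xcol <- matrix(0, nrow(ci$idx), kk * Cin)
  for (j in seq_len(kk)) {
    Xcol[, ((j - 1L) * Cin + 1L):(j * Cin)] <- Xa[ci$idx[, j], , drop = FALSE]
  }
  list(out = add_cols(Xcol %*% W, b), cache = list(Xcol = Xcol, ci = ci, Cin = Cin))
}

conv_backward <- function(dY, cache, W) {
  ci <- cache$ci; Cin <- cache$Cin
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, W)
  dX <- matrix(0, ci$N, Cin)
  kk <- ncol(ci$idx)
  for (j in seq_len(kk)) {
    tgt <- ci$idx[, j]
    ok <- tgt <= ci$N
    cols <- ((j - 1L) * Cin + 1L):(j * Cin)
    dX[tgt[ok], ] <- dX[tgt[ok], , drop = FALSE] + dXcol[ok, cols, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- Adam optimiser ----------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# elementwise sum of two same-shaped gradient lists
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (k in names(b)) a[[k]] <- a[[k]] + b[[k]]
  a
}

grad_scale <- function(a, s) lapply(a, function(x) x * s)
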
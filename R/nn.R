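# Low-level neural building blocks with hand-derived reverse-mode gradients.
# All token activations are stored as (B*T) x D matrices, sample-major: the
# rows of sample b are ((b-1)*T + 1):(b*T). BLAS matrix products do the heavy
# lifting; only the T x T attention softmax loops over (sample, head).

# sinusoidal positional encoding, position 0 = class token
pe_sinusoidal <- function(n_tokens, d) {
  pos <- seq_len(n_tokens) - 1
  pe <- matrix(0, n_tokens, d)
  half <- d %/% 2
  for (i in seq_len(half)) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pe[, 2 * i - 1] <- sin(pos * freq)
    pe[, 2 * i] <- cos(pos * freq)
  }
  if (d %% 2 == 1) pe[, d] <- sin(pos / 10000^((d - 1) / d))
  pe
}

# column-broadcast helpers: g has length D, X is n x D
add_bias <- function(X, b) X + rep(b, each = nrow(X))
scale_cols <- function(X, g) X * rep(g, each = nrow(X))

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  invstd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * invstd
  list(y = add_bias(scale_cols(xhat, g), b), xhat = xhat, invstd = invstd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- scale_cols(dy, g)
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

gelu_fwd <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# inverted dropout; mask already carries the 1/(1-p) scale
dropout_mask <- function(n, p) {
  if (p <= 0) return(NULL)
  (stats::runif(n) >= p) / (1 - p)
}
apply_mask <- function(X, mask) {
  if (is.null(mask)) X else X * mask
}

init_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

# fan-in scaled init for linear maps (rows = input dim)
init_linear <- function(nr, nc) init_mat(nr, nc, sd = 1 / sqrt(nr))

# one pre-norm transformer encoder block:
#   X' = X + Drop(MSA(LN1(X)));  X_out = X' + Drop(FFN(LN2(X')))
block_forward <- function(X, bp, n_heads, p_drop, B, T, training, keep_cache) {
  D <- ncol(X)
  dh <- D %/% n_heads
  scal <- 1 / sqrt(dh)
  ln1 <- layernorm_fwd(X, bp$ln1_g, bp$ln1_b)
  Q <- add_bias(ln1$y %*% bp$Wq, bp$bq)
  K <- add_bias(ln1$y %*% bp$Wk, bp$bk)
  V <- add_bias(ln1$y %*% bp$Wv, bp$bv)
  Ohead <- matrix(0, nrow(X), D)
  Aarr <- if (keep_cache) array(0, c(T, T, n_heads, B)) else NULL
  for (b in seq_len(B)) {
    rb <- ((b - 1) * T + 1):(b * T)
    for (h in seq_len(n_heads)) {
      ch <- ((h - 1) * dh + 1):(h * dh)
      S <- (Q[rb, ch, drop = FALSE] %*% t(K[rb, ch, drop = FALSE])) * scal
      S <- S - apply(S, 1, max)
      E <- exp(S)
      A <- E / rowSums(E)
      if (keep_cache) Aarr[, , h, b] <- A
      Ohead[rb, ch] <- A %*% V[rb, ch, drop = FALSE]
    }
  }
  attn <- add_bias(Ohead %*% bp$Wo, bp$bo)
  m1 <- if (training) dropout_mask(length(attn), p_drop) else NULL
  X2 <- X + apply_mask(attn, m1)
  ln2 <- layernorm_fwd(X2, bp$ln2_g, bp$ln2_b)
  H1 <- add_bias(ln2$y %*% bp$W1, bp$b1)
  G1 <- gelu_fwd(H1)
  m2 <- if (training) dropout_mask(length(G1), p_drop) else NULL
  G1d <- apply_mask(G1, m2)
  H2 <- add_bias(G1d %*% bp$W2, bp$b2)
  m3 <- if (training) dropout_mask(length(H2), p_drop) else NULL
  Xout <- X2 + apply_mask(H2, m3)
  cache <- NULL
  if (keep_cache) {
    cache <- list(ln1 = ln1, Q = Q, K = K, V = V, A = Aarr, Ohead = Ohead,
                  m1 = m1, X2 = X2, ln2 = ln2, H1 = H1, G1 = G1, G1d = G1d,
                  m2 = m2, m3 = m3, B = B, T = T)
  }
  list(X = Xout, cache = cache)
}

block_backward <- function(dXout, cache, bp, n_heads) {
  D <- ncol(dXout)
  dh <- D %/% n_heads
  scal <- 1 / sqrt(dh)
  B <- cache$B; T <- cache$T
  # FFN path
  dH2 <- apply_mask(dXout, cache$m3)
  dW2 <- crossprod(cache$G1d, dH2)
  db2 <- colSums(dH2)
  dG1 <- apply_mask(dH2 %*% t(bp$W2), cache$m2)
  dH1 <- dG1 * gelu_grad(cache$H1)
  dW1 <- crossprod(cache$ln2$y, dH1)
  db1 <- colSums(dH1)
  dY2 <- dH1 %*% t(bp$W1)
  ln2b <- layernorm_bwd(dY2, cache$ln2, bp$ln2_g)
  dX2 <- dXout + ln2b$dx
  # attention path
  dattn <- apply_mask(dX2, cache$m1)
  dWo <- crossprod(cache$Ohead, dattn)
  dbo <- colSums(dattn)
  dOhead <- dattn %*% t(bp$Wo)
  dQ <- matrix(0, nrow(dXout), D)
  dK <- matrix(0, nrow(dXout), D)
  dV <- matrix(0, nrow(dXout), D)
  for (b in seq_len(B)) {
    rb <- ((b - 1) * T + 1):(b * T)
    for (h in seq_len(n_heads)) {
      ch <- ((h - 1) * dh + 1):(h * dh)
      A <- cache$A[, , h, b]
      dOh <- dOhead[rb, ch, drop = FALSE]
      dA <- dOh %*% t(cache$V[rb, ch, drop = FALSE])
      dV[rb, ch] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A)) * scal
      dQ[rb, ch] <- dS %*% cache$K[rb, ch, drop = FALSE]
      dK[rb, ch] <- crossprod(dS, cache$Q[rb, ch, drop = FALSE])
    }
  }
  Y1 <- cache$ln1$y
  dWq <- crossprod(Y1, dQ); dbq <- colSums(dQ)
  dWk <- crossprod(Y1, dK); dbk <- colSums(dK)
  dWv <- crossprod(Y1, dV); dbv <- colSums(dV)
  dY1 <- dQ %*% t(bp$Wq) + dK %*% t(bp$Wk) + dV %*% t(bp$Wv)
  ln1b <- layernorm_bwd(dY1, cache$ln1, bp$ln1_g)
  dXin <- dX2 + ln1b$dx
  list(dX = dXin,
       grads = list(ln1_g = ln1b$dg, ln1_b = ln1b$db,
                    Wq = dWq, bq = dbq, Wk = dWk, bk = dbk,
                    Wv = dWv, bv = dbv, Wo = dWo, bo = dbo,
                    ln2_g = ln2b$dg, ln2_b = ln2b$db,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# recursive helpers over nested parameter lists
tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}
tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}
tree_sum <- function(f, x) {
  if (is.list(x)) sum(vapply(x, function(e) tree_sum(f, e), numeric(1))) else f(x)
}

softmax_rows <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

cross_entropy <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dlogits = dZ / n, probs = P)
}

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
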
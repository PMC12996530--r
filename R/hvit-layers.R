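# Neural-network layer primitives with analytic forward/backward passes.
# Feature maps are arrays [H, W, C]; token matrices are [n_tokens, dim].
# Every backward function consumes the cache produced by its forward pass.
# Gradient correctness is checked against central finite differences in the
# test suite.

# ---- convolution (same padding) via im2col -------------------------------

conv_plan <- function(H, W, kh, kw) {
  Hp <- H + kh - 1L; Wp <- W + kw - 1L
  ii <- rep(seq_len(H), times = W)      # output positions, column-major
  jj <- rep(seq_len(W), each = H)
  idx <- matrix(0L, kh * kw, H * W)
  for (b in seq_len(kw)) {
    for (a in seq_len(kh)) {
      idx[(b - 1L) * kh + a, ] <- (jj + b - 2L) * Hp + (ii + a - 1L)
    }
  }
  list(idx = idx, Hp = Hp, Wp = Wp, o_r = (kh - 1L) %/% 2L,
       o_c = (kw - 1L) %/% 2L, H = H, W = W, kh = kh, kw = kw)
}

# x [H,W,Cin]; W_mat [Cout, kh*kw*Cin]; b [Cout]
conv2d_forward <- function(x, W_mat, b, plan) {
  H <- plan$H; W <- plan$W
  cin <- if (length(dim(x)) == 3L) dim(x)[3] else 1L
  khkw <- plan$kh * plan$kw
  xp <- array(0, c(plan$Hp, plan$Wp, cin))
  xp[plan$o_r + seq_len(H), plan$o_c + seq_len(W), ] <- x
  cols <- matrix(0, khkw * cin, H * W)
  for (c in seq_len(cin)) {
    plane <- xp[, , c]
    cols[(c - 1L) * khkw + seq_len(khkw), ] <- plane[plan$idx]
  }
  out <- W_mat %*% cols + b            # [Cout, HW]
  y <- array(as.vector(t(out)), c(H, W, nrow(W_mat)))
  list(y = y, cache = list(cols = cols, cin = cin, plan = plan))
}

conv2d_backward <- function(dy, W_mat, cache) {
  plan <- cache$plan; cin <- cache$cin
  H <- plan$H; W <- plan$W; khkw <- plan$kh * plan$kw
  cout <- nrow(W_mat)
  dy_mat <- t(matrix(dy, H * W, cout))         # [Cout, HW]
  dW <- dy_mat %*% t(cache$cols)
  db <- rowSums(dy_mat)
  dcols <- t(W_mat) %*% dy_mat                  # [khkw*Cin, HW]
  dxp <- array(0, c(plan$Hp, plan$Wp, cin))
  for (c in seq_len(cin)) {
    plane <- matrix(0, plan$Hp, plan$Wp)
    block <- dcols[(c - 1L) * khkw + seq_len(khkw), , drop = FALSE]
    for (r in seq_len(khkw)) {
      # within one kernel offset all target indices are distinct
      plane[plan$idx[r, ]] <- plane[plan$idx[r, ]] + block[r, ]
    }
    dxp[, , c] <- plane
  }
  dx <- dxp[plan$o_r + seq_len(H), plan$o_c + seq_len(W), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# ---- 2x2 max pooling ------------------------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  a <- x[seq(1L, H, 2L), seq(1L, W, 2L), , drop = FALSE]
  out <- a
  src <- array(1L, dim(a))
  k <- 2L
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
    cand <- x[seq(1L + off[1], H, 2L), seq(1L + off[2], W, 2L), , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    src[upd] <- k
    k <- k + 1L
  }
  list(y = out, cache = list(src = src, H = H, W = W, C = C))
}

maxpool2_backward <- function(dy, cache) {
  H <- cache$H; W <- cache$W; C <- cache$C
  Hh <- H %/% 2L; Wh <- W %/% 2L
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  i <- rep(seq_len(Hh), times = Wh * C)
  j <- rep(rep(seq_len(Wh), each = Hh), times = C)
  ch <- rep(seq_len(C), each = Hh * Wh)
  src <- as.vector(cache$src)
  ro <- vapply(offs, `[`, integer(1), 1L)[src]
  co <- vapply(offs, `[`, integer(1), 2L)[src]
  lin <- (ch - 1L) * H * W + (2L * j - 2L + co) * H + (2L * i - 1L + ro)
  dx <- array(0, c(H, W, C))
  dx[lin] <- as.vector(dy)
  dx
}

# ---- activations ----------------------------------------------------------

leaky_forward <- function(x, slope) {
  y <- ifelse(x > 0, x, slope * x)
  list(y = y, cache = x)
}

leaky_backward <- function(dy, cache, slope) {
  dy * ifelse(cache > 0, 1, slope)
}

softplus_fwd <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- dense ----------------------------------------------------------------

linear_forward <- function(x, W, b) {
  list(y = sweep(x %*% W, 2L, b, "+"), cache = x)
}

linear_backward <- function(dy, W, cache) {
  list(dx = dy %*% t(W), dW = t(cache) %*% dy, db = colSums(dy))
}

# ---- layer normalization (per token over the feature dimension) ----------

layernorm_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, g, "*")
  y <- sweep(y, 2L, b, "+")
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_backward <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2L, cache$g, "*")
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = dg, db = db)
}

# ---- attention ------------------------------------------------------------

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# x [n, d]; Wq/Wk/Wv/Wo [d, d]; n_heads divides d
mha_forward <- function(x, p, n_heads) {
  d <- ncol(x); dk <- d %/% n_heads
  Q <- sweep(x %*% p$Wq, 2L, p$bq, "+")
  K <- sweep(x %*% p$Wk, 2L, p$bk, "+")
  V <- sweep(x %*% p$Wv, 2L, p$bv, "+")
  O <- matrix(0, nrow(x), d)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
    A <- softmax_rows(S)
    O[, cols] <- A %*% V[, cols, drop = FALSE]
    A_list[[h]] <- A
  }
  y <- sweep(O %*% p$Wo, 2L, p$bo, "+")
  list(y = y, cache = list(x = x, Q = Q, K = K, V = V, O = O, A = A_list,
                           n_heads = n_heads, dk = dk))
}

mha_backward <- function(dy, p, cache) {
  x <- cache$x; dk <- cache$dk; n_heads <- cache$n_heads
  dWo <- t(cache$O) %*% dy
  dbo <- colSums(dy)
  dO <- dy %*% t(p$Wo)
  dQ <- matrix(0, nrow(x), ncol(x))
  dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dV[, cols] <- t(A) %*% dOh
    dA <- dOh %*% t(cache$V[, cols, drop = FALSE])
    dS <- A * (dA - rowSums(dA * A))
    dS <- dS / sqrt(dk)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE]
  }
  list(dx = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv),
       dWq = t(x) %*% dQ, dbq = colSums(dQ),
       dWk = t(x) %*% dK, dbk = colSums(dK),
       dWv = t(x) %*% dV, dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}
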
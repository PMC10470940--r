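# Neural-network primitives with hand-derived backward passes. All layers
# operate on plain numeric matrices; parameters live in named lists so the
# optimiser can treat them uniformly.

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# ---- gated recurrent unit ------------------------------------------------
# Recurrence (element-wise, d_hat[0] = 0):
#   r_i = sigmoid(Wr d_i + Ur d_hat[i-1])
#   b_i = sigmoid(Wb d_i + Ub d_hat[i-1])
#   o_i = tanh(Wh d_i + Ud (r_i * d_hat[i-1]))
#   d_hat[i] = b_i * d_hat[i-1] + (1 - b_i) * o_i
# Parameter matrices are stored input-major (nin x F) so a whole sequence can
# be projected with one matrix product.

gruInit <- function(nin, nout) {
  list(Wr = .glorot(nin, nout), Wb = .glorot(nin, nout),
       Wh = .glorot(nin, nout), Ur = .glorot(nout, nout),
       Ub = .glorot(nout, nout), Ud = .glorot(nout, nout))
}

# X: t x nin. Returns H (t x F) plus caches for the backward pass.
gruForward <- function(X, p) {
  t <- nrow(X)
  F <- ncol(p$Wr)
  Pr <- X %*% p$Wr
  Pb <- X %*% p$Wb
  Ph <- X %*% p$Wh
  H <- matrix(0, t, F)
  R <- matrix(0, t, F); B <- matrix(0, t, F); O <- matrix(0, t, F)
  hPrev <- numeric(F)
  for (i in seq_len(t)) {
    r <- sigmoid(Pr[i, ] + drop(hPrev %*% p$Ur))
    b <- sigmoid(Pb[i, ] + drop(hPrev %*% p$Ub))
    o <- tanh(Ph[i, ] + drop((r * hPrev) %*% p$Ud))
    h <- b * hPrev + (1 - b) * o
    R[i, ] <- r; B[i, ] <- b; O[i, ] <- o; H[i, ] <- h
    hPrev <- h
  }
  list(H = H, R = R, B = B, O = O, X = X)
}

# dH: t x F gradient w.r.t. every hidden state. Returns parameter grads and
# the gradient w.r.t. the input sequence.
gruBackward <- function(cache, p, dH) {
  X <- cache$X
  t <- nrow(X)
  F <- ncol(dH)
  g <- lapply(p, function(m) matrix(0, nrow(m), ncol(m)))
  dX <- matrix(0, nrow(X), ncol(X))
  carry <- numeric(F)
  for (i in rev(seq_len(t))) {
    hPrev <- if (i == 1) numeric(F) else cache$H[i - 1, ]
    r <- cache$R[i, ]; b <- cache$B[i, ]; o <- cache$O[i, ]
    dh <- dH[i, ] + carry
    do <- dh * (1 - b)
    db <- dh * (hPrev - o)
    dhPrev <- dh * b
    dao <- do * (1 - o^2)
    g$Wh <- g$Wh + outer(X[i, ], dao)
    drh <- drop(dao %*% t(p$Ud))          # grad w.r.t. (r * hPrev)
    g$Ud <- g$Ud + outer(r * hPrev, dao)
    dr <- drh * hPrev
    dhPrev <- dhPrev + drh * r
    dar <- dr * r * (1 - r)
    dab <- db * b * (1 - b)
    g$Wr <- g$Wr + outer(X[i, ], dar)
    g$Wb <- g$Wb + outer(X[i, ], dab)
    g$Ur <- g$Ur + outer(hPrev, dar)
    g$Ub <- g$Ub + outer(hPrev, dab)
    dhPrev <- dhPrev + drop(dar %*% t(p$Ur)) + drop(dab %*% t(p$Ub))
    dX[i, ] <- drop(dar %*% t(p$Wr)) + drop(dab %*% t(p$Wb)) +
      drop(dao %*% t(p$Wh))
    carry <- dhPrev
  }
  list(grads = g, dX = dX)
}

# ---- depthwise 1D convolution (same padding, stride 1) -------------------
# X: channels x length; K: channels x kernel; each channel has its own
# kernel and bias.

conv1dForward <- function(X, K, bias) {
  n <- nrow(X); len <- ncol(X); ks <- ncol(K)
  half <- (ks - 1) %/% 2
  Xpad <- cbind(matrix(0, n, half), X, matrix(0, n, ks - 1 - half))
  out <- matrix(0, n, len)
  for (s in seq_len(ks)) {
    out <- out + K[, s] * Xpad[, s:(s + len - 1), drop = FALSE]
  }
  out + bias
}

conv1dBackward <- function(X, K, dOut) {
  n <- nrow(X); len <- ncol(X); ks <- ncol(K)
  half <- (ks - 1) %/% 2
  Xpad <- cbind(matrix(0, n, half), X, matrix(0, n, ks - 1 - half))
  dK <- matrix(0, n, ks)
  dXpad <- matrix(0, n, ncol(Xpad))
  for (s in seq_len(ks)) {
    cols <- s:(s + len - 1)
    dK[, s] <- rowSums(dOut * Xpad[, cols, drop = FALSE])
    dXpad[, cols] <- dXpad[, cols] + K[, s] * dOut
  }
  list(dK = dK, dBias = rowSums(dOut),
       dX = dXpad[, (half + 1):(half + len), drop = FALSE])
}

# ---- batch normalisation over rows (one statistic per column) ------------

batchnormForward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  list(Y = sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`),
       xhat = xhat, istd = istd, mu = mu, var = v)
}

batchnormBackward <- function(cache, gamma, dY) {
  m <- nrow(dY)
  xhat <- cache$xhat
  dGamma <- colSums(dY * xhat)
  dBeta <- colSums(dY)
  dXhat <- sweep(dY, 2, gamma, `*`)
  dX <- sweep(dXhat - matrix(colMeans(dXhat), m, ncol(dY), byrow = TRUE) -
                xhat * matrix(colMeans(dXhat * xhat), m, ncol(dY),
                              byrow = TRUE),
              2, cache$istd, `*`)
  list(dX = dX, dGamma = dGamma, dBeta = dBeta)
}

# ---- Adam ----------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# accumulate grads2 into grads1 (missing entries created)
.addGrads <- function(g1, g2) {
  for (nm in names(g2)) {
    g1[[nm]] <- if (is.null(g1[[nm]])) g2[[nm]] else g1[[nm]] + g2[[nm]]
  }
  g1
}

.scaleGrads <- function(g, s) lapply(g, function(x) x * s)
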
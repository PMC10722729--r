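# Internal neural-network primitives.
#
# Feature maps are (channels x length) matrices. Every forward returns the
# output plus whatever the matching backward needs; backwards return the
# input gradient and parameter gradients. All layers are stride-1 with
# zero "same" padding so temporal length is preserved throughout.

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow = nrow, ncol = ncol)
}

# --- 1-D convolution via im2col -------------------------------------------

# W: (C_out, C_in * k) with k odd; columns of the im2col matrix ordered by
# temporal offset (block j holds the input shifted by j - 1 - pad).
conv1d_fwd <- function(X, W, b, k) {
  C_in <- nrow(X); L <- ncol(X)
  pad <- (k - 1L) %/% 2L
  Xp <- cbind(matrix(0, C_in, pad), X, matrix(0, C_in, pad))
  Xc <- matrix(0, C_in * k, L)
  for (j in seq_len(k))
    Xc[((j - 1L) * C_in + 1L):(j * C_in), ] <- Xp[, j:(j + L - 1L), drop = FALSE]
  list(Y = W %*% Xc + b, Xc = Xc)
}

conv1d_bwd <- function(dY, W, Xc, C_in, k) {
  L <- ncol(dY)
  pad <- (k - 1L) %/% 2L
  dW <- dY %*% t(Xc)
  db <- rowSums(dY)
  dXc <- crossprod(W, dY)
  dXp <- matrix(0, C_in, L + 2L * pad)
  for (j in seq_len(k)) {
    cols <- j:(j + L - 1L)
    dXp[, cols] <- dXp[, cols] + dXc[((j - 1L) * C_in + 1L):(j * C_in), , drop = FALSE]
  }
  list(dX = dXp[, (pad + 1L):(pad + L), drop = FALSE], dW = dW, db = db)
}

# --- temporal max pooling (k = 3, same padding) ---------------------------

maxpool1d_fwd <- function(X, k = 3L) {
  C <- nrow(X); L <- ncol(X)
  pad <- (k - 1L) %/% 2L
  Xp <- cbind(matrix(-Inf, C, pad), X, matrix(-Inf, C, pad))
  Y <- matrix(-Inf, C, L)
  argj <- matrix(0L, C, L)
  for (j in seq_len(k)) {
    S <- Xp[, j:(j + L - 1L), drop = FALSE]
    upd <- S > Y          # strict: ties resolve to the earliest offset
    Y[upd] <- S[upd]
    argj[upd] <- j
  }
  list(Y = Y, argj = argj)
}

maxpool1d_bwd <- function(dY, argj, k = 3L) {
  C <- nrow(dY); L <- ncol(dY)
  pad <- (k - 1L) %/% 2L
  dXp <- matrix(0, C, L + 2L * pad)
  for (j in seq_len(k)) {
    mask <- argj == j
    cols <- j:(j + L - 1L)
    dXp[, cols] <- dXp[, cols] + dY * mask
  }
  dXp[, (pad + 1L):(pad + L), drop = FALSE]
}

# --- per-channel normalization over the temporal axis ---------------------

instnorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  Xhat <- Xc * inv_sd
  list(Y = Xhat * gamma + beta, Xhat = Xhat, Xc = Xc, inv_sd = inv_sd)
}

instnorm_bwd <- function(dY, cache, gamma) {
  L <- ncol(dY)
  dXhat <- dY * gamma
  dvar <- rowSums(dXhat * cache$Xc) * (-0.5) * cache$inv_sd^3
  dmu <- -rowSums(dXhat) * cache$inv_sd
  dX <- dXhat * cache$inv_sd + (dvar * 2 / L) * cache$Xc + dmu / L
  list(dX = dX, dgamma = rowSums(dY * cache$Xhat), dbeta = rowSums(dY))
}

relu <- function(X) {
  X[X < 0] <- 0
  X
}

# --- dense layer on row-major design matrices -----------------------------

linear_fwd <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

linear_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- Adam over nested parameter lists -------------------------------------

zeros_like <- function(params) rapply(params, function(x) x * 0, how = "replace")

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  t <- state$t + 1L
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in seq_along(p)) {  # positional: parameter lists may be unnamed
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r[[1L]]; m[[nm]] <- r[[2L]]; v[[nm]] <- r[[3L]]
      }
      list(p, m, v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p, m, v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r[[1L]], state = list(m = r[[2L]], v = r[[3L]], t = t))
}

# elementwise sum of two parameter lists with identical structure
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}
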
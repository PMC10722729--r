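#' Self-attention parameters
#'
#' Three linear projections sharing input dimension `d_node` and output
#' dimension `d_k`, used to derive the query, key and value matrices from
#' the same input.
#'
#' @param d_node Input feature dimension.
#' @param d_k Projection dimension (defaults to `d_node`).
#' @param scale Divide attention scores by `sqrt(d_k)` (default TRUE).
#' @param seed Integer seed for initialization.
#' @return Object of class `attention_params` with `Wq`, `Wk`, `Wv`.
#' @export
attention_params <- function(d_node, d_k = d_node, scale = TRUE, seed = 1L) {
  if (d_k < 1) stop("d_k must be >= 1", call. = FALSE)
  p <- with_seed(seed, list(Wq = glorot(d_node, d_k), Wk = glorot(d_node, d_k),
                            Wv = glorot(d_node, d_k)))
  structure(c(p, list(scale = scale)), class = "attention_params")
}

#' Scaled dot-product self-attention
#'
#' Computes `softmax((X Wq)(X Wk)^T / sqrt(d_k)) (X Wv)`: each output row is
#' a convex combination of the value rows, with weights derived from
#' query-key similarity. Every attention-weight row sums to 1.
#'
#' @param X Input matrix (n x d_node), one row per item.
#' @param params An `attention_params` object.
#' @param weights Also return the attention-weight matrix.
#' @return The (n x d_k) output matrix, or (with `weights = TRUE`) a list
#'   with elements `output` and `weights`.
#' @export
self_attention <- function(X, params, weights = FALSE) {
  stopifnot(inherits(params, "attention_params"))
  X <- rbind(X)  # promote a single vector to a 1-row matrix
  Q <- X %*% params$Wq
  K <- X %*% params$Wk
  V <- X %*% params$Wv
  S <- Q %*% t(K)
  if (isTRUE(params$scale)) S <- S / sqrt(ncol(Q))
  W <- softmax_rows(S)
  out <- W %*% V
  if (weights) list(output = out, weights = W) else out
}

softmax_rows <- function(S) {
  S <- exp(S - apply(S, 1L, max))
  S / rowSums(S)
}

# --- vectorized pair attention (rows of E1/E2 are the two pair members) ----

attn_pair_fwd <- function(E1, E2, p) {
  Q1 <- E1 %*% p$Wq; Q2 <- E2 %*% p$Wq
  K1 <- E1 %*% p$Wk; K2 <- E2 %*% p$Wk
  V1 <- E1 %*% p$Wv; V2 <- E2 %*% p$Wv
  sc <- if (isTRUE(p$scale)) 1 / sqrt(ncol(Q1)) else 1
  s11 <- rowSums(Q1 * K1) * sc; s12 <- rowSums(Q1 * K2) * sc
  s21 <- rowSums(Q2 * K1) * sc; s22 <- rowSums(Q2 * K2) * sc
  m1 <- pmax(s11, s12); e11 <- exp(s11 - m1); e12 <- exp(s12 - m1)
  m2 <- pmax(s21, s22); e21 <- exp(s21 - m2); e22 <- exp(s22 - m2)
  a11 <- e11 / (e11 + e12); a12 <- 1 - a11
  a21 <- e21 / (e21 + e22); a22 <- 1 - a21
  list(O1 = a11 * V1 + a12 * V2, O2 = a21 * V1 + a22 * V2,
       Q1 = Q1, Q2 = Q2, K1 = K1, K2 = K2, V1 = V1, V2 = V2,
       a11 = a11, a12 = a12, a21 = a21, a22 = a22, sc = sc)
}

attn_pair_bwd <- function(dO1, dO2, E1, E2, p, cc) {
  dV1 <- cc$a11 * dO1 + cc$a21 * dO2
  dV2 <- cc$a12 * dO1 + cc$a22 * dO2
  da11 <- rowSums(dO1 * cc$V1); da12 <- rowSums(dO1 * cc$V2)
  da21 <- rowSums(dO2 * cc$V1); da22 <- rowSums(dO2 * cc$V2)
  # softmax jacobian per 2-way row
  r1 <- cc$a11 * da11 + cc$a12 * da12
  ds11 <- cc$a11 * (da11 - r1); ds12 <- cc$a12 * (da12 - r1)
  r2 <- cc$a21 * da21 + cc$a22 * da22
  ds21 <- cc$a21 * (da21 - r2); ds22 <- cc$a22 * (da22 - r2)
  sc <- cc$sc
  dQ1 <- (ds11 * cc$K1 + ds12 * cc$K2) * sc
  dQ2 <- (ds21 * cc$K1 + ds22 * cc$K2) * sc
  dK1 <- (ds11 * cc$Q1 + ds21 * cc$Q2) * sc
  dK2 <- (ds12 * cc$Q1 + ds22 * cc$Q2) * sc
  list(dE1 = dQ1 %*% t(p$Wq) + dK1 %*% t(p$Wk) + dV1 %*% t(p$Wv),
       dE2 = dQ2 %*% t(p$Wq) + dK2 %*% t(p$Wk) + dV2 %*% t(p$Wv),
       grads = list(Wq = crossprod(E1, dQ1) + crossprod(E2, dQ2),
                    Wk = crossprod(E1, dK1) + crossprod(E2, dK2),
                    Wv = crossprod(E1, dV1) + crossprod(E2, dV2)))
}

#' Relational scorer parameters (FRN / NTN)
#'
#' Holds the `k` bilinear tensor slices `W[, , i]` (each d x d), the
#' standard-layer matrix `V` (k x 2d) applied to the concatenated pair, the
#' bias `b` (length k) and, for the NTN scalar scorer, the output projection
#' `u` (length k).
#'
#' @param d Entity feature dimension.
#' @param k Number of tensor slices (default 8).
#' @param seed Integer seed.
#' @return Object of class `frn_params`.
#' @export
frn_params <- function(d, k = 8L, seed = 1L) {
  with_seed(seed, structure(
    list(W = array(stats::runif(d * d * k, -1, 1) * sqrt(3 / d) / sqrt(d),
                   dim = c(d, d, k)),
         V = glorot(k, 2L * d), b = numeric(k),
         u = stats::runif(k, -1, 1) / sqrt(k)),
    class = c("frn_params", "list")))
}

check_pair_dims <- function(e1, e2, params) {
  d <- dim(params$W)[1L]
  if (length(e1) != length(e2))
    stop("e1 and e2 must have equal dimension", call. = FALSE)
  if (length(e1) != d)
    stop("entity dimension ", length(e1), " does not match tensor slices (",
         d, ")", call. = FALSE)
  invisible(d)
}

#' Neural Tensor Network relational score
#'
#' The classic bilinear scorer
#' `u' tanh(h + V [e1; e2] + b)` with `h_i = e1' W[, , i] e2`: a bilinear
#' tensor layer relating the two entity vectors multiplicatively, plus a
#' standard linear layer on their concatenation.
#'
#' @param e1,e2 Entity feature vectors of equal dimension `d`.
#' @param params An `frn_params` object.
#' @return A single numeric score.
#' @export
ntn_score <- function(e1, e2, params) {
  check_pair_dims(e1, e2, params)
  k <- dim(params$W)[3L]
  h <- vapply(seq_len(k), function(i) drop(e1 %*% params$W[, , i] %*% e2),
              numeric(1))
  sum(params$u * tanh(h + drop(params$V %*% c(e1, e2)) + params$b))
}

#' Cosine similarity with a zero-norm convention
#'
#' `(e1 . e2) / (|e1| |e2|)`; if either vector has zero norm there is no
#' direction information and the similarity is defined as 0.
#'
#' @param e1,e2 Numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(e1, e2) {
  n1 <- sqrt(sum(e1^2)); n2 <- sqrt(sum(e2^2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(e1 * e2) / (n1 * n2)
}

#' Feature relational reasoning score
#'
#' The relational scorer used for pair fusion: per tensor slice `i`,
#' `tanh((e1 + e2)' W[, , i] (e1 - e2) + (V [e1; e2])_i cos(e1, e2) + b_i)`.
#' The bilinear term contracts the pair's sum against its difference, so it
#' is exactly antisymmetric under swapping `e1` and `e2` and vanishes at
#' `e1 = e2`; the standard layer is weighted by the pair's cosine
#' similarity, injecting explicit direction information.
#'
#' @inheritParams ntn_score
#' @return Numeric vector of length `k`, entries strictly inside (-1, 1).
#' @export
frn_score <- function(e1, e2, params) {
  check_pair_dims(e1, e2, params)
  k <- dim(params$W)[3L]
  s <- e1 + e2; m <- e1 - e2
  h <- vapply(seq_len(k), function(i) drop(s %*% params$W[, , i] %*% m),
              numeric(1))
  tanh(h + drop(params$V %*% c(e1, e2)) * cosine_similarity(e1, e2) + params$b)
}

# --- vectorized relational fwd/bwd over m pairs ---------------------------

relational_fwd <- function(E1, E2, p, ntn = FALSE) {
  m <- nrow(E1); d <- ncol(E1); k <- dim(p$W)[3L]
  A <- if (ntn) E1 else E1 + E2   # left factor
  B <- if (ntn) E2 else E1 - E2   # right factor
  H <- matrix(0, m, k)
  for (i in seq_len(k)) H[, i] <- rowSums((A %*% p$W[, , i]) * B)
  lin <- cbind(E1, E2) %*% t(p$V)
  if (ntn) {
    cosv <- rep(1, m)  # no cosine weighting in the NTN form
  } else {
    n1 <- sqrt(rowSums(E1^2)); n2 <- sqrt(rowSums(E2^2))
    nn <- n1 * n2
    cosv <- ifelse(nn > 0, rowSums(E1 * E2) / nn, 0)
  }
  pre <- H + lin * cosv + matrix(p$b, m, k, byrow = TRUE)
  Fk <- tanh(pre)
  list(Fk = Fk, A = A, B = B, lin = lin, cosv = cosv, ntn = ntn)
}

relational_bwd <- function(dF, E1, E2, p, cc) {
  m <- nrow(E1); d <- ncol(E1); k <- dim(p$W)[3L]
  dpre <- dF * (1 - cc$Fk^2)
  db <- colSums(dpre)
  dlin <- dpre * cc$cosv
  dV <- crossprod(dlin, cbind(E1, E2))
  dE1 <- dlin %*% p$V[, seq_len(d), drop = FALSE]
  dE2 <- dlin %*% p$V[, d + seq_len(d), drop = FALSE]
  dA <- matrix(0, m, d); dB <- matrix(0, m, d)
  dW <- array(0, dim = dim(p$W))
  for (i in seq_len(k)) {
    di <- dpre[, i]
    dA <- dA + di * (cc$B %*% t(p$W[, , i]))
    dB <- dB + di * (cc$A %*% p$W[, , i])
    dW[, , i] <- crossprod(cc$A, di * cc$B)
  }
  if (cc$ntn) {
    dE1 <- dE1 + dA
    dE2 <- dE2 + dB
  } else {
    dE1 <- dE1 + dA + dB
    dE2 <- dE2 + dA - dB
    # cosine path (zero-norm rows contribute no gradient)
    dcos <- rowSums(dpre * cc$lin)
    n1 <- sqrt(rowSums(E1^2)); n2 <- sqrt(rowSums(E2^2))
    nn <- n1 * n2
    ok <- nn > 0
    if (any(ok)) {
      w <- ifelse(ok, dcos / nn, 0)
      cv <- cc$cosv
      dE1 <- dE1 + w * E2 - ifelse(ok, dcos * cv / pmax(n1^2, .Machine$double.eps), 0) * E1
      dE2 <- dE2 + w * E1 - ifelse(ok, dcos * cv / pmax(n2^2, .Machine$double.eps), 0) * E2
    }
  }
  list(dE1 = dE1, dE2 = dE2,
       grads = list(W = dW, V = dV, b = db, u = p$u * 0))
}

#' Multi-label classifier parameters
#'
#' A fully connected classifier on the fused pair representation: hidden
#' linear stage with ReLU, then a linear map to 7 logits (one per
#' interaction type) squashed by a sigmoid.
#'
#' @param d_in Fused pair-representation dimension.
#' @param hidden Hidden width (default 32).
#' @param seed Integer seed.
#' @return Object of class `classifier_params`.
#' @export
classifier_params <- function(d_in, hidden = 32L, seed = 1L) {
  n_lab <- length(ppi_labels())
  with_seed(seed, structure(
    list(W1 = glorot(d_in, hidden), b1 = numeric(hidden),
         W2 = glorot(hidden, n_lab), b2 = numeric(n_lab)),
    class = c("classifier_params", "list")))
}

classifier_fwd <- function(U, p) {
  H1pre <- linear_fwd(U, p$W1, p$b1)
  H1 <- relu(H1pre)
  logits <- linear_fwd(H1, p$W2, p$b2)
  list(prob = sigmoid(logits), H1 = H1, H1pre = H1pre)
}

classifier_bwd <- function(dlogits, U, p, cc) {
  l2 <- linear_bwd(dlogits, cc$H1, p$W2)
  dH1 <- l2$dX * (cc$H1pre > 0)
  l1 <- linear_bwd(dH1, U, p$W1)
  list(dU = l1$dX,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}

#' Classify a fused pair representation into interaction types
#'
#' @param pair_repr Numeric vector, the fused representation of one protein
#'   pair (or a matrix with one row per pair).
#' @param params A `classifier_params` object.
#' @param threshold Per-label decision cutoff (default 0.5); a label is
#'   predicted when its probability is `>= threshold`.
#' @return List with `prob` (7 probabilities in (0,1), named by interaction
#'   type; a matrix for matrix input) and `labels` (character vector of
#'   predicted types, or a list of them for matrix input).
#' @export
classify <- function(pair_repr, params, threshold = 0.5) {
  stopifnot(inherits(params, "classifier_params"))
  U <- rbind(pair_repr)
  if (ncol(U) != nrow(params$W1))
    stop("pair representation dimension ", ncol(U),
         " does not match classifier input ", nrow(params$W1), call. = FALSE)
  prob <- classifier_fwd(U, params)$prob
  colnames(prob) <- ppi_labels()
  sets <- apply(prob >= threshold, 1L, function(r) ppi_labels()[r],
                simplify = FALSE)
  if (nrow(U) == 1L && !is.matrix(pair_repr))
    list(prob = prob[1L, ], labels = sets[[1L]])
  else list(prob = prob, labels = sets)
}

#' Multi-task binary cross-entropy loss
#'
#' Summed over all pairs and all 7 label tasks:
#' `-y log(p) - (1 - y) log(1 - p)`, with probabilities clamped to
#' `[eps, 1 - eps]`.
#'
#' @param y_hat Probability matrix (n_pairs x 7).
#' @param y Binary ground-truth matrix of the same shape.
#' @param eps Clamping constant (default 1e-7).
#' @return A single nonnegative number.
#' @export
bce_multilabel_loss <- function(y_hat, y, eps = 1e-7) {
  y_hat <- rbind(y_hat); y <- rbind(y)
  if (!all(dim(y_hat) == dim(y)))
    stop("y_hat and y must have identical shape", call. = FALSE)
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  sum(-y * log(p) - (1 - y) * log(1 - p))
}
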
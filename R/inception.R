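#' Parameters for the Inception-style sequence encoder
#'
#' Builds the parameter stack of the protein node feature encoder: a chain of
#' `n_submodules` identical Inception sub-modules, each concatenating four
#' length-preserving branches — 1-D convolutions with kernel sizes 1, 3 and
#' 5, plus a temporal max-pooling branch followed by a 1x1 projection — with
#' per-branch channel normalization (optional) and ReLU. A final global
#' average pooling over the temporal axis collapses any sequence length to a
#' fixed node feature dimension `d_node = 3 * channels + pool_channels`.
#'
#' @param c_in Input channels (13 for the residue matrix).
#' @param channels Output channels of each convolution branch.
#' @param pool_channels Output channels of the max-pool branch projection.
#' @param n_submodules Number of stacked sub-modules (default 4).
#' @param norm Apply per-channel normalization over the temporal axis within
#'   each branch.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `inception_params`.
#' @export
inception_params <- function(c_in = 13L, channels = 32L,
                             pool_channels = channels, n_submodules = 4L,
                             norm = TRUE, seed = 1L) {
  stopifnot(channels >= 1, n_submodules >= 1)
  kernels <- c(1L, 3L, 5L)
  d_out <- 3L * channels + pool_channels
  blocks <- with_seed(seed, {
    lapply(seq_len(n_submodules), function(i) {
      ci <- if (i == 1L) c_in else d_out
      # kernel size is implied by the branch name (c1/c3/c5; pool = 1x1
      # projection) so parameter leaves stay purely numeric for the optimizer
      branch <- function(k, ch) {
        p <- list(W = glorot(ch, ci * k), b = numeric(ch))
        if (norm) { p$gamma <- rep(1, ch); p$beta <- numeric(ch) }
        p
      }
      list(c1 = branch(1L, channels), c3 = branch(3L, channels),
           c5 = branch(5L, channels), pool = branch(1L, pool_channels))
    })
  })
  structure(list(blocks = blocks, c_in = as.integer(c_in),
                 channels = as.integer(channels),
                 pool_channels = as.integer(pool_channels),
                 n_submodules = as.integer(n_submodules),
                 norm = norm, d_node = as.integer(d_out)),
            class = "inception_params")
}

branch_kernel <- c(c1 = 1L, c3 = 3L, c5 = 5L, pool = 1L)

# one branch: conv (or maxpool + 1x1 conv) -> [norm] -> relu, with caches
branch_fwd <- function(X, p, k, norm, is_pool) {
  cache <- list()
  if (is_pool) {
    mp <- maxpool1d_fwd(X, 3L)
    cache$argj <- mp$argj
    X <- mp$Y
  }
  cv <- conv1d_fwd(X, p$W, p$b, k)
  cache$Xc <- cv$Xc
  Y <- cv$Y
  if (norm) {
    nf <- instnorm_fwd(Y, p$gamma, p$beta)
    cache$norm <- nf[c("Xhat", "Xc", "inv_sd")]
    Y <- nf$Y
  }
  cache$pre_relu <- Y
  list(Y = relu(Y), cache = cache)
}

branch_bwd <- function(dY, p, k, cache, norm, is_pool, c_in) {
  dY <- dY * (cache$pre_relu > 0)
  g <- list(W = NULL, b = NULL)
  if (norm) {
    nb <- instnorm_bwd(dY, cache$norm, p$gamma)
    g$gamma <- nb$dgamma; g$beta <- nb$dbeta
    dY <- nb$dX
  }
  cb <- conv1d_bwd(dY, p$W, cache$Xc, c_in, k)
  g$W <- cb$dW; g$b <- cb$db
  dX <- cb$dX
  if (is_pool) dX <- maxpool1d_bwd(dX, cache$argj, 3L)
  list(dX = dX, grads = g[names(p)])
}

block_fwd <- function(X, bp, norm) {
  brs <- list(c1 = branch_fwd(X, bp$c1, 1L, norm, FALSE),
              c3 = branch_fwd(X, bp$c3, 3L, norm, FALSE),
              c5 = branch_fwd(X, bp$c5, 5L, norm, FALSE),
              pool = branch_fwd(X, bp$pool, 1L, norm, TRUE))
  list(Y = do.call(rbind, lapply(brs, `[[`, "Y")),
       caches = lapply(brs, `[[`, "cache"))
}

block_bwd <- function(dY, bp, caches, norm, c_in) {
  chs <- c(nrow(bp$c1$W), nrow(bp$c3$W), nrow(bp$c5$W), nrow(bp$pool$W))
  off <- cumsum(c(0L, chs))
  dX <- NULL
  grads <- list()
  nms <- c("c1", "c3", "c5", "pool")
  for (i in seq_along(nms)) {
    nm <- nms[i]
    rows <- (off[i] + 1L):off[i + 1L]
    r <- branch_bwd(dY[rows, , drop = FALSE], bp[[nm]], branch_kernel[[nm]],
                    caches[[nm]], norm, nm == "pool", c_in)
    grads[[nm]] <- r$grads
    dX <- if (is.null(dX)) r$dX else dX + r$dX
  }
  list(dX = dX, grads = grads)
}

#' Apply one Inception sub-module
#'
#' Channel-wise concatenation of the kernel-size 1, 3 and 5 convolution
#' branches and the max-pool branch, each preserving the temporal length.
#'
#' @param X Input feature map, a (channels x length) matrix.
#' @param params An `inception_params` object.
#' @param block Index of the sub-module to apply (default 1).
#' @return Feature map with `d_node` rows and `ncol(X)` columns.
#' @export
inception_block <- function(X, params, block = 1L) {
  stopifnot(inherits(params, "inception_params"))
  if (!is.matrix(X) || ncol(X) < 1L) stop("input must have length >= 1", call. = FALSE)
  bp <- params$blocks[[block]]
  expected <- ncol(bp$c1$W)  # k = 1, so this is the block's input channels
  if (nrow(X) != expected)
    stop("input has ", nrow(X), " channels; sub-module ", block,
         " expects ", expected, call. = FALSE)
  block_fwd(X, bp, params$norm)$Y
}

encoder_fwd <- function(X, params, pooling = c("mean", "max")) {
  pooling <- match.arg(pooling)
  caches <- vector("list", params$n_submodules)
  inputs <- vector("list", params$n_submodules)
  for (i in seq_len(params$n_submodules)) {
    inputs[[i]] <- X
    r <- block_fwd(X, params$blocks[[i]], params$norm)
    caches[[i]] <- r$caches
    X <- r$Y
  }
  if (pooling == "max") {
    arg <- max.col(X, ties.method = "first")
    z <- X[cbind(seq_len(nrow(X)), arg)]
  } else {
    arg <- NULL
    z <- rowMeans(X)
  }
  list(z = z, caches = caches, inputs = inputs, L = ncol(X),
       pooling = pooling, arg = arg)
}

encoder_bwd <- function(dz, params, fwd) {
  L <- fwd$L
  if (fwd$pooling == "max") {
    dY <- matrix(0, nrow = length(dz), ncol = L)
    dY[cbind(seq_along(dz), fwd$arg)] <- dz
  } else
  dY <- matrix(dz / L, nrow = length(dz), ncol = L)  # global average pooling
  grads <- vector("list", params$n_submodules)
  for (i in rev(seq_len(params$n_submodules))) {
    c_in <- nrow(fwd$inputs[[i]])
    r <- block_bwd(dY, params$blocks[[i]], fwd$caches[[i]], params$norm, c_in)
    grads[[i]] <- r$grads
    dY <- r$dX
  }
  grads
}

#' Encode a protein as a fixed-dimension node feature vector
#'
#' Runs the residue matrix through the stacked Inception sub-modules and
#' collapses the temporal axis by global pooling (average by default,
#' maximum by option), so proteins of any length map to vectors of
#' identical dimension `params$d_node`.
#'
#' @param X Residue matrix from [encode_sequence()] (13 x L).
#' @param params An `inception_params` object.
#' @param pooling `"mean"` (global average, default) or `"max"`.
#' @return Numeric vector of length `params$d_node`.
#' @export
encode_protein <- function(X, params, pooling = c("mean", "max")) {
  stopifnot(inherits(params, "inception_params"))
  if (nrow(X) != params$c_in)
    stop("residue matrix has ", nrow(X), " rows; encoder expects ",
         params$c_in, call. = FALSE)
  encoder_fwd(X, params, pooling)$z
}
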
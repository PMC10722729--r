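#' Build the undirected training PPI graph
#'
#' Proteins are nodes and training interactions are edges; multi-label edges
#' collapse to a single structural edge. Proteins without any training edge
#' (e.g. test-only proteins) are kept as isolated nodes so they remain
#' encodable — at inference their graph update sees only their own encoder
#' feature. Test edges must never be passed here: the adjacency is the
#' training partition's, which is what prevents information leakage into
#' inductive evaluation.
#'
#' @param proteins data.frame (`id`, `sequence`); defines the node set and
#'   order.
#' @param node_features Numeric matrix (n_proteins x d_node) of encoder
#'   features, rows in `proteins$id` order (rownames, if present, must match).
#' @param train_edges Edge data.frame; endpoints must all be known proteins.
#' @return Object of class `ppi_graph`: list with `node_ids`, symmetric
#'   zero-diagonal `adjacency` matrix, and `features`.
#' @export
build_ppi_graph <- function(proteins, node_features, train_edges) {
  ids <- proteins$id
  stopifnot(is.matrix(node_features), nrow(node_features) == length(ids))
  if (!is.null(rownames(node_features)) && !identical(rownames(node_features), ids))
    stop("node_features rownames do not match proteins$id", call. = FALSE)
  ia <- match(train_edges$protein_a, ids)
  ib <- match(train_edges$protein_b, ids)
  if (anyNA(ia) || anyNA(ib)) {
    missing <- unique(c(train_edges$protein_a[is.na(ia)],
                        train_edges$protein_b[is.na(ib)]))
    stop("edge endpoint(s) without a node feature: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(ia, ib)] <- 1
  A[cbind(ib, ia)] <- 1
  diag(A) <- 0
  structure(list(node_ids = ids, adjacency = A, features = node_features),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("PPI graph: %d nodes, %d edges, %d-dim node features\n",
              length(x$node_ids), sum(x$adjacency) / 2, ncol(x$features)))
  invisible(x)
}

#' Parameters of one GIN layer
#'
#' The Graph Isomorphism Network update aggregates by summation —
#' `MLP((1 + eps) * g_p + sum of neighbour features)` — with a learnable
#' `eps` (initialized at 0) and a two-layer ReLU MLP mapping `d_node` to
#' `d_node` (hidden width `d_node`).
#'
#' @param d_node Node feature dimension.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `gin_params` (also a plain parameter list usable
#'   by the optimizer): `eps`, `W1`, `b1`, `W2`, `b2`.
#' @export
gin_params <- function(d_node, seed = 1L) {
  with_seed(seed, structure(
    list(eps = 0, W1 = glorot(d_node, d_node), b1 = numeric(d_node),
         W2 = glorot(d_node, d_node), b2 = numeric(d_node)),
    class = c("gin_params", "list")))
}

gin_fwd <- function(Z, A, p) {
  S <- (1 + p$eps) * Z + A %*% Z
  H1pre <- linear_fwd(S, p$W1, p$b1)
  H1 <- relu(H1pre)
  list(H = linear_fwd(H1, p$W2, p$b2), S = S, H1 = H1, H1pre = H1pre)
}

gin_bwd <- function(dH, Z, A, p, cache) {
  l2 <- linear_bwd(dH, cache$H1, p$W2)
  dH1 <- l2$dX * (cache$H1pre > 0)
  l1 <- linear_bwd(dH1, cache$S, p$W1)
  dS <- l1$dX
  dZ <- (1 + p$eps) * dS + A %*% dS  # A symmetric, so A^T = A
  list(dZ = dZ,
       grads = list(eps = sum(dS * Z), W1 = l1$dW, b1 = l1$db,
                    W2 = l2$dW, b2 = l2$db))
}

#' One GIN feature-propagation step
#'
#' Applies the sum-aggregation update to every node of the graph:
#' `MLP((1 + eps) * g_p + sum_{p' in N(p)} g_{p'})`. With `identity = TRUE`
#' the MLP is bypassed, which reduces the update to the closed form
#' `((1 + eps) I + A) %*% features` — useful for verification.
#'
#' @param graph A `ppi_graph`.
#' @param params A `gin_params` object.
#' @param identity Bypass the MLP (default FALSE).
#' @return Updated node-feature matrix, same shape as `graph$features`.
#' @export
gin_update <- function(graph, params, identity = FALSE) {
  stopifnot(inherits(graph, "ppi_graph"))
  Z <- graph$features
  if (ncol(Z) != nrow(params$W1))
    stop("feature dimension ", ncol(Z), " does not match MLP input ",
         nrow(params$W1), call. = FALSE)
  S <- (1 + params$eps) * Z + graph$adjacency %*% Z
  if (identity) return(S)
  gin_fwd(Z, graph$adjacency, params)$H
}
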
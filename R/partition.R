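#' Random 80/20 train-test split of an edge set
#'
#' Holds out a uniformly sampled `round(ratio * nrow(edges))` test edges.
#'
#' @param edges Edge data.frame (`protein_a`, `protein_b`, optionally `labels`).
#' @param ratio Test fraction in (0, 1); default 0.2.
#' @param seed Integer seed; the partition is reproducible under it.
#' @return A `ppi_split` object with `train`, `test`, and the
#'   homologous/unknown stratification of the test edges.
#' @export
random_split <- function(edges, ratio = 0.2, seed = 1L) {
  check_split_input(edges, ratio)
  n <- nrow(edges)
  n_test <- round(ratio * n)
  idx <- with_seed(seed, sample.int(n, n_test))
  pairs <- edges[, c("protein_a", "protein_b")]
  train <- pairs[setdiff(seq_len(n), idx), , drop = FALSE]
  test <- pairs[sort(idx), , drop = FALSE]
  row.names(train) <- row.names(test) <- NULL
  new_ppi_split("random", seed, train, test)
}

#' BFS/DFS traversal-based inductive train-test split
#'
#' Emulates the inductive link-prediction protocol: starting from a random
#' root protein, the protein graph is traversed breadth-first (`"bfs"`) or
#' depth-first (`"dfs"`); every edge incident to a visited node is assigned to
#' the test set, and traversal stops as soon as the test set reaches
#' `ratio * nrow(edges)` edges (it may overshoot by the last visited node's
#' incident edges). If a connected component is exhausted first, traversal
#' restarts from a new random unvisited root. Test edges therefore cluster
#' around the visited neighbourhood, forcing prediction for proteins unseen
#' (or sparsely seen) in training.
#'
#' @param edges Edge data.frame.
#' @param scheme `"bfs"` or `"dfs"`.
#' @inheritParams random_split
#' @return A `ppi_split` object.
#' @export
traversal_split <- function(edges, scheme = c("bfs", "dfs"), ratio = 0.2,
                            seed = 1L) {
  scheme <- match.arg(scheme)
  check_split_input(edges, ratio)
  n <- nrow(edges)
  target <- ratio * n
  nodes <- unique(c(edges$protein_a, edges$protein_b))
  ia <- match(edges$protein_a, nodes)
  ib <- match(edges$protein_b, nodes)
  # incident edge indices per node
  inc <- split(rep(seq_len(n), 2L), c(ia, ib))
  neigh <- split(c(ib, ia), c(ia, ib))

  test_mark <- logical(n)
  n_test <- 0L
  done <- FALSE
  with_seed(seed, {
    visited <- logical(length(nodes))
    root_order <- sample.int(length(nodes))
    ri <- 1L
    while (!done) {
      while (ri <= length(nodes) && visited[root_order[ri]]) ri <- ri + 1L
      if (ri > length(nodes)) break  # every node visited
      frontier <- root_order[ri]
      visited[frontier] <- TRUE
      while (length(frontier) > 0 && !done) {
        v <- frontier[1L]
        frontier <- frontier[-1L]
        # claim the visited node's incident edges one at a time so the test
        # set stops exactly on reaching the target count
        for (e in inc[[as.character(v)]]) {
          if (!test_mark[e]) {
            test_mark[e] <- TRUE
            n_test <- n_test + 1L
            if (n_test >= target) {
              done <- TRUE
              break
            }
          }
        }
        nb <- neigh[[as.character(v)]]
        nb <- nb[!visited[nb]]
        if (length(nb) > 0 && !done) {
          visited[nb] <- TRUE
          # bfs appends to the queue tail; dfs pushes onto the stack head
          frontier <- if (scheme == "bfs") c(frontier, nb) else c(nb, frontier)
        }
      }
    }
  })
  if (n_test < target)
    stop("graph exhausted before reaching the requested test ratio", call. = FALSE)
  pairs <- edges[, c("protein_a", "protein_b")]
  train <- pairs[!test_mark, , drop = FALSE]
  test <- pairs[test_mark, , drop = FALSE]
  row.names(train) <- row.names(test) <- NULL
  new_ppi_split(scheme, seed, train, test)
}

#' Stratify test edges into homologous and unknown subsets
#'
#' A test edge is *homologous* iff both endpoints occur in at least one
#' training edge (the model has seen both proteins inside the training
#' graph); otherwise it is *unknown* — at least one endpoint never appears in
#' training, the harder inductive case.
#'
#' @param train_edges,test_edges Edge data.frames.
#' @return List with data.frames `test_homologous` and `test_unknown`,
#'   a disjoint partition of `test_edges`.
#' @export
stratify_test <- function(train_edges, test_edges) {
  seen <- unique(c(train_edges$protein_a, train_edges$protein_b))
  homol <- test_edges$protein_a %in% seen & test_edges$protein_b %in% seen
  out <- list(test_homologous = test_edges[homol, , drop = FALSE],
              test_unknown = test_edges[!homol, , drop = FALSE])
  row.names(out$test_homologous) <- row.names(out$test_unknown) <- NULL
  out
}

check_split_input <- function(edges, ratio) {
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b") %in% names(edges)))
  if (nrow(edges) < 2) stop("need at least 2 edges to split", call. = FALSE)
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1)
    stop("ratio must be a single number in (0, 1)", call. = FALSE)
  invisible(TRUE)
}

# evaluate `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
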
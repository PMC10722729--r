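test_that("graph construction keeps isolated nodes and collapses label multiplicity", {
  prot <- data.frame(id = c("p1", "p2", "p3"),
                     sequence = c("MKV", "ACD", "WWW"))
  feats <- matrix(rnorm(9), 3, 3)
  ed <- make_edges("p1-p2:binding")
  g <- build_ppi_graph(prot, feats, ed)
  expect_equal(sum(g$adjacency["p3", ]), 0)  # isolated but present
  expect_equal(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))

  # the same structural pair with two different labels is still one edge
  ed2 <- rbind(make_edges("p1-p2:binding"), make_edges("p1-p2:catalysis"))
  g2 <- build_ppi_graph(prot, feats, ed2)
  expect_equal(sum(g2$adjacency) / 2, 1)
})

test_that("graph construction names missing endpoints", {
  prot <- data.frame(id = c("p1", "p2"), sequence = c("MKV", "ACD"))
  expect_error(build_ppi_graph(prot, matrix(0, 2, 4), make_edges("p1-p9:binding")),
               "p9")
})

test_that("adjacency is symmetric with zero diagonal on random edge sets", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    prot <- data.frame(id = sprintf("n%02d", 1:n),
                       sequence = rep("ACDEF", n))
    pairs <- t(combn(prot$id, 2))
    take <- sample(nrow(pairs), min(nrow(pairs), n * 2), replace = FALSE)
    ed <- data.frame(protein_a = pairs[take, 1], protein_b = pairs[take, 2],
                     labels = I(replicate(length(take), "binding",
                                          simplify = FALSE)))
    g <- build_ppi_graph(prot, matrix(0, n, 2), ed)
    expect_equal(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 0))
    expect_equal(sum(g$adjacency) / 2, length(take))
  }
})

test_that("GIN sum aggregation matches the hand-computed examples", {
  prot <- data.frame(id = c("a", "b", "c"), sequence = rep("ACD", 3))
  feats <- matrix(c(1, 2, 3), 3, 1)
  g <- build_ppi_graph(prot, feats, make_edges("a-b:binding", "a-c:binding"))
  p <- gin_params(1L, seed = 1L)
  p$eps <- 0
  out <- gin_update(g, p, identity = TRUE)
  expect_equal(unname(out["a", 1]), 1 * 1 + 2 + 3)  # (1+0)*own + neighbour sum

  # isolated node depends only on its own feature
  g2 <- build_ppi_graph(prot, matrix(c(2, 5, 7), 3, 1), make_edges("b-c:binding"))
  p$eps <- 0.5
  out2 <- gin_update(g2, p, identity = TRUE)
  expect_equal(unname(out2["a", 1]), 1.5 * 2)
})

test_that("GIN with identity MLP equals the (1+eps)I + A closed form", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(4:20, 1); d <- sample(2:6, 1)
    A <- matrix(0, n, n)
    pairs <- which(upper.tri(A), arr.ind = TRUE)
    take <- pairs[sample(nrow(pairs), min(nrow(pairs), 2 * n)), , drop = FALSE]
    A[take] <- 1; A <- A + t(A)
    feats <- matrix(rnorm(n * d), n, d)
    ids <- sprintf("n%02d", 1:n)
    dimnames(A) <- list(ids, ids)
    g <- structure(list(node_ids = ids, adjacency = A, features = feats),
                   class = "ppi_graph")
    p <- gin_params(d, seed = rep)
    p$eps <- runif(1, -0.5, 0.5)
    oracle <- ((1 + p$eps) * diag(n) + A) %*% feats
    expect_equal(gin_update(g, p, identity = TRUE), oracle,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("GIN output is invariant to neighbour enumeration order", {
  prot <- data.frame(id = sprintf("p%d", 1:6), sequence = rep("ACD", 6))
  feats <- matrix(rnorm(12), 6, 2)
  ed <- make_edges("p1-p2:binding", "p1-p3:binding", "p1-p4:binding",
                   "p5-p6:binding")
  p <- gin_params(2L, seed = 2L)
  g1 <- build_ppi_graph(prot, feats, ed)
  set.seed(5)
  g2 <- build_ppi_graph(prot, feats, ed[sample(nrow(ed)), ])
  expect_equal(gin_update(g1, p), gin_update(g2, p))
})

test_that("GIN is permutation-equivariant", {
  set.seed(41)
  n <- 8L; d <- 3L
  prot <- data.frame(id = sprintf("p%d", 1:n), sequence = rep("ACD", n))
  feats <- matrix(rnorm(n * d), n, d)
  ed <- make_edges("p1-p2:binding", "p2-p3:binding", "p3-p4:binding",
                   "p4-p5:binding", "p1-p6:binding", "p7-p8:binding")
  p <- gin_params(d, seed = 3L)
  out <- gin_update(build_ppi_graph(prot, feats, ed), p)

  perm <- sample(n)
  prot2 <- prot[perm, , drop = FALSE]
  out_perm <- gin_update(build_ppi_graph(prot2, feats[perm, , drop = FALSE], ed), p)
  expect_equal(out_perm, out[perm, , drop = FALSE], ignore_attr = TRUE)
})
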
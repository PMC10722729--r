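test_that("random splits hold out exactly the rounded test fraction, reproducibly", {
  dat <- tiny_dataset(seed = 3L, n_proteins = 30L, n_edges = 100L)
  sp <- random_split(dat$edges, 0.2, seed = 9L)
  expect_equal(nrow(sp$test), 20L)
  expect_equal(nrow(sp$train), 80L)
  sp2 <- random_split(dat$edges, 0.2, seed = 9L)
  expect_identical(sp$test, sp2$test)
  expect_false(identical(sp$test, random_split(dat$edges, 0.2, seed = 10L)$test))
  expect_error(random_split(dat$edges, 1.2), "ratio")
})

test_that("all three schemes produce covering, disjoint partitions at the ratio", {
  key <- function(df) paste(df$protein_a, df$protein_b)
  for (seed in 1:3) {
    dat <- tiny_dataset(seed = seed, n_proteins = 40L, n_edges = 120L)
    for (scheme in c("random", "bfs", "dfs")) {
      sp <- if (scheme == "random") random_split(dat$edges, 0.2, seed)
            else traversal_split(dat$edges, scheme, 0.2, seed)
      expect_setequal(c(key(sp$train), key(sp$test)), key(dat$edges))
      expect_length(intersect(key(sp$train), key(sp$test)), 0L)
      expect_gte(nrow(sp$test), 24L)   # ceiling stop rule at 0.2 * 120
      expect_lte(nrow(sp$test), 25L)
      # strata partition the test set
      expect_setequal(c(key(sp$test_homologous), key(sp$test_unknown)),
                      key(sp$test))
      expect_length(intersect(key(sp$test_homologous), key(sp$test_unknown)), 0L)
    }
  }
})

test_that("traversal splits follow the visited-node incident-edge rule", {
  # path graph p1-p2-p3-p4-p5: at ratio 0.25 the first visited node
  # contributes exactly one incident edge
  path_edges <- make_edges("p1-p2:binding", "p2-p3:binding",
                           "p3-p4:binding", "p4-p5:binding")
  sp <- traversal_split(path_edges, "bfs", ratio = 0.25, seed = 1L)
  expect_equal(nrow(sp$test), 1L)
  # the single test edge is incident to some root protein of the path
  expect_equal(nrow(sp$train), 3L)

  # star graph: whatever the root, edges accrue one at a time and stop at 2
  star_edges <- make_edges(paste0("leaf", 1:10, "-ctr:binding"))
  sp2 <- traversal_split(star_edges, "bfs", ratio = 0.2, seed = 4L)
  expect_equal(nrow(sp2$test), 2L)

  # triangle: BFS and DFS from the same seeded root agree
  tri <- make_edges("a-b:binding", "b-c:binding", "a-c:binding")
  b <- traversal_split(tri, "bfs", ratio = 0.5, seed = 2L)
  d <- traversal_split(tri, "dfs", ratio = 0.5, seed = 2L)
  expect_identical(b$test, d$test)
})

test_that("traversal splits restart on multi-component graphs", {
  comp1 <- make_edges("a-b:binding", "b-c:binding")
  comp2 <- make_edges("x-y:binding", "y-z:binding", "x-z:binding")
  sp <- traversal_split(rbind(comp1, comp2), "dfs", ratio = 0.9, seed = 3L)
  expect_equal(nrow(sp$test), 5L)  # ceiling(0.9 * 5) forces both components
})

test_that("identical seeds reproduce identical splits through file round-trips", {
  dat <- tiny_dataset(seed = 5L, n_proteins = 25L, n_edges = 60L)
  for (scheme in c("bfs", "dfs")) {
    s1 <- traversal_split(dat$edges, scheme, 0.2, seed = 7L)
    s2 <- traversal_split(dat$edges, scheme, 0.2, seed = 7L)
    f1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_split(s1, f1); write_split(s2, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("homologous/unknown stratification follows endpoint visibility", {
  train <- make_edges("a-b:binding", "b-c:binding")
  # both endpoints of (a,c) occur in training edges -> homologous
  st <- stratify_test(train, make_edges("a-c:binding"))
  expect_equal(nrow(st$test_homologous), 1L)
  expect_equal(nrow(st$test_unknown), 0L)
  # b2 appears nowhere in training -> unknown
  st2 <- stratify_test(make_edges("a-b:binding"), make_edges("a-b2:binding"))
  expect_equal(nrow(st2$test_unknown), 1L)
  expect_equal(nrow(st2$test_homologous), 0L)
})
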
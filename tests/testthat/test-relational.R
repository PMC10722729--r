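test_that("self-attention handles the single-row and symmetric cases", {
  p <- attention_params(4L, 3L, seed = 2L)
  x <- matrix(rnorm(4), 1, 4)
  expect_equal(self_attention(x, p), x %*% p$Wv)

  X <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  r <- self_attention(X, p, weights = TRUE)
  expect_equal(r$weights, matrix(0.5, 2, 2))
})

test_that("attention weight rows are a convex combination over value rows", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(2:7, 1); d <- sample(2:6, 1)
    p <- attention_params(d, sample(2:5, 1), seed = rep)
    X <- matrix(rnorm(n * d), n, d)
    r <- self_attention(X, p, weights = TRUE)
    expect_equal(rowSums(r$weights), rep(1, n), tolerance = 1e-12)
    expect_true(all(r$weights >= 0))
    expect_equal(r$output, r$weights %*% (X %*% p$Wv))
  }
})

test_that("attention rejects a zero projection dimension", {
  expect_error(attention_params(4L, 0L), "d_k")
})

test_that("NTN score matches the hand examples and a triple-loop oracle", {
  # all parameters zero -> 0
  p0 <- frn_params(2L, 1L, seed = 1L)
  p0$W[] <- 0; p0$V[] <- 0; p0$b[] <- 0; p0$u[] <- 0
  expect_equal(ntn_score(c(1, 2), c(3, 4), p0), 0)

  # k = 1, identity slice, orthogonal one-hots -> tanh(0) = 0
  p1 <- p0
  p1$W[, , 1] <- diag(2)
  p1$u[] <- 1
  expect_equal(ntn_score(c(1, 0), c(0, 1), p1), 0)

  set.seed(13)
  for (rep in 1:6) {
    d <- sample(2:8, 1); k <- sample(1:4, 1)
    p <- frn_params(d, k, seed = rep + 100L)
    e1 <- rnorm(d); e2 <- rnorm(d)
    h <- numeric(k)
    for (i in seq_len(k))
      for (a in seq_len(d))
        for (b in seq_len(d))
          h[i] <- h[i] + e1[a] * p$W[a, b, i] * e2[b]
    oracle <- sum(p$u * tanh(h + drop(p$V %*% c(e1, e2)) + p$b))
    expect_equal(ntn_score(e1, e2, p), oracle, tolerance = 1e-10)
  }
  expect_error(ntn_score(1:3, 1:2, frn_params(3L, 2L)), "equal dimension")
})

test_that("cosine similarity follows the zero-norm convention", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(2, 4)), 1)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
})

test_that("FRN score: identity pair, zero parameters, and open range", {
  p <- frn_params(3L, 2L, seed = 5L)
  e <- c(0.3, -1, 2)
  # e1 = e2: bilinear term vanishes, cosine is 1
  expect_equal(frn_score(e, e, p),
               tanh(drop(p$V %*% c(e, e)) + p$b))

  p0 <- p; p0$W[] <- 0; p0$V[] <- 0; p0$b[] <- 0
  expect_equal(frn_score(c(1, 2, 3), c(4, 5, 6), p0), c(0, 0))

  set.seed(17)
  for (rep in 1:5) {
    out <- frn_score(rnorm(3), rnorm(3), p)
    expect_true(all(out > -1 & out < 1))
  }
})

test_that("the FRN bilinear term is antisymmetric under argument swap", {
  set.seed(19)
  for (rep in 1:8) {
    d <- sample(2:8, 1); k <- sample(1:4, 1)
    p <- frn_params(d, k, seed = rep + 50L)
    p$V[] <- 0; p$b[] <- 0  # isolate the bilinear term inside tanh
    e1 <- rnorm(d); e2 <- rnorm(d)
    expect_equal(atanh(frn_score(e1, e2, p)),
                 -atanh(frn_score(e2, e1, p)), tolerance = 1e-10)
    # and the direct identity: (e1+e2)' W (e1-e2) on each slice
    bil <- vapply(seq_len(k), function(i)
      drop((e1 + e2) %*% p$W[, , i] %*% (e1 - e2)), numeric(1))
    expect_equal(atanh(frn_score(e1, e2, p)), bil, tolerance = 1e-10)
  }
})

test_that("classifier emits 7 open-interval probabilities and thresholds labels", {
  p <- classifier_params(5L, hidden = 6L, seed = 3L)
  r <- classify(rnorm(5), p)
  expect_length(r$prob, 7L)
  expect_named(r$prob, ppi_labels())
  expect_true(all(r$prob > 0 & r$prob < 1))
  expect_true(all(r$labels %in% ppi_labels()))
  expect_equal(classify(rnorm(5), p, threshold = 1.0)$labels, character(0))
  expect_error(classify(rnorm(3), p), "dimension")
})

test_that("multi-task BCE matches closed forms and is nonnegative", {
  y <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 0, 0, 1, 1), 2, 7)
  expect_equal(bce_multilabel_loss(matrix(0.5, 2, 7), y), 2 * 7 * log(2),
               tolerance = 1e-9)
  eps <- 1e-7
  expect_lt(bce_multilabel_loss(y, y), 2 * 7 * abs(log(1 - eps)) + 1e-12)
  set.seed(23)
  for (rep in 1:5) {
    yh <- matrix(runif(14), 2, 7)
    yy <- matrix(rbinom(14, 1, 0.3), 2, 7)
    expect_gte(bce_multilabel_loss(yh, yy), 0)
  }
  expect_error(bce_multilabel_loss(matrix(0.5, 2, 7), matrix(1, 2, 6)),
               "identical shape")
})

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

test_that("FRN gradients match central finite differences", {
  ns <- asNamespace("seqppi")
  set.seed(29)
  for (rep in 1:4) {
    d <- sample(2:6, 1); k <- sample(1:3, 1)
    p <- frn_params(d, k, seed = rep + 200L)
    e1 <- rnorm(d); e2 <- rnorm(d)
    w <- rnorm(k)  # project the k outputs to a scalar for the check
    fw <- ns$relational_fwd(rbind(e1), rbind(e2), p)
    bw <- ns$relational_bwd(rbind(w), rbind(e1), rbind(e2), p, fw)

    f_e1 <- function(x) sum(w * frn_score(x, e2, p))
    f_e2 <- function(x) sum(w * frn_score(e1, x, p))
    expect_equal(drop(bw$dE1), num_grad(f_e1, e1), tolerance = 1e-4)
    expect_equal(drop(bw$dE2), num_grad(f_e2, e2), tolerance = 1e-4)

    f_W <- function(x) { q <- p; q$W[] <- x; sum(w * frn_score(e1, e2, q)) }
    expect_equal(as.numeric(bw$grads$W), num_grad(f_W, as.numeric(p$W)),
                 tolerance = 1e-4)
    f_V <- function(x) { q <- p; q$V[] <- x; sum(w * frn_score(e1, e2, q)) }
    expect_equal(as.numeric(bw$grads$V), num_grad(f_V, as.numeric(p$V)),
                 tolerance = 1e-4)
    f_b <- function(x) { q <- p; q$b[] <- x; sum(w * frn_score(e1, e2, q)) }
    expect_equal(as.numeric(bw$grads$b), num_grad(f_b, p$b), tolerance = 1e-4)
  }
})

test_that("BCE gradients match central finite differences", {
  set.seed(31)
  for (rep in 1:4) {
    n <- sample(2:4, 1)
    yh <- matrix(runif(n * 7, 0.05, 0.95), n, 7)
    y <- matrix(rbinom(n * 7, 1, 0.3), n, 7)
    analytic <- (yh - y) / (yh * (1 - yh))
    numeric <- matrix(num_grad(function(x)
      bce_multilabel_loss(matrix(x, n, 7), y), as.numeric(yh)), n, 7)
    expect_equal(analytic, numeric, tolerance = 1e-4)
  }
})
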
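test_that("training records one history row per epoch with finite decreasing loss", {
  dat <- tiny_dataset(seed = 3L)
  ctl <- tiny_control(epochs = 10L)
  fit <- ppi_fit(dat$proteins, dat$edges, control = ctl)
  h <- fit$history
  expect_equal(nrow(h), 10L)
  expect_true(all(is.finite(h$loss)))
  expect_true(all(!is.na(h$train_micro_f1)))  # eval_every = 1
  # optimization sanity on noise-free data
  expect_lt(h$loss[10], h$loss[1])
})

test_that("fits are deterministic under a fixed seed", {
  dat <- tiny_dataset(seed = 5L)
  f1 <- ppi_fit(dat$proteins, dat$edges, control = tiny_control())
  f2 <- ppi_fit(dat$proteins, dat$edges, control = tiny_control())
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$theta, f2$theta)
  f3 <- ppi_fit(dat$proteins, dat$edges, control = tiny_control(seed = 6L))
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("deleting test edges after splitting leaves the trained model identical", {
  dat <- tiny_dataset(seed = 7L)
  sp <- random_split(dat$edges, 0.2, seed = 2L)
  fit_full <- ppi_fit(dat$proteins, dat$edges, sp, tiny_control())

  key <- function(df) paste(df$protein_a, df$protein_b)
  edges_train_only <- dat$edges[key(dat$edges) %in% key(sp$train), , drop = FALSE]
  fit_blind <- ppi_fit(dat$proteins, edges_train_only, sp, tiny_control())

  expect_identical(fit_full$adjacency, fit_blind$adjacency)
  expect_identical(fit_full$theta, fit_blind$theta)
})

test_that("every ablation combination trains and evaluates without code changes", {
  dat <- tiny_dataset(seed = 9L, n_proteins = 10L, n_edges = 14L,
                      length_range = c(20L, 35L))
  combos <- expand.grid(inception = c(TRUE, FALSE),
                        attention = c(TRUE, FALSE),
                        scorer = c("frn", "ntn", "none"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    ctl <- tiny_control(epochs = 2L,
                        use_inception = combos$inception[i],
                        use_attention = combos$attention[i],
                        use_frn = combos$scorer[i] == "frn",
                        use_ntn = combos$scorer[i] == "ntn")
    fit <- ppi_fit(dat$proteins, dat$edges, control = ctl)
    expect_true(all(is.finite(fit$history$loss)), info = paste(combos[i, ], collapse = "/"))
    ev <- ppi_evaluate(fit)
    expect_s3_class(ev$overall, "ppi_metrics")
  }
  expect_error(ppi_control(use_frn = TRUE, use_ntn = TRUE), "mutually exclusive")
})

test_that("predictions preserve order, repeat deterministically, and stay in (0,1)", {
  dat <- tiny_dataset(seed = 11L)
  fit <- ppi_fit(dat$proteins, dat$edges, control = tiny_control())
  pairs <- dat$edges[c(3, 1, 3), c("protein_a", "protein_b")]
  pr <- predict(fit, pairs)
  expect_equal(nrow(pr), 3L)
  expect_equal(pr$protein_a, pairs$protein_a)
  expect_equal(unlist(pr[1, ppi_labels()]), unlist(pr[3, ppi_labels()]))
  p <- as.matrix(pr[, ppi_labels()])
  expect_true(all(p > 0 & p < 1))
  expect_error(predict(fit, data.frame(protein_a = "nope", protein_b = "P001")),
               "nope")
})

test_that("evaluation conserves counts and flags empty strata", {
  dat <- tiny_dataset(seed = 13L)
  sp <- random_split(dat$edges, 0.2, seed = 3L)
  fit <- ppi_fit(dat$proteins, dat$edges, sp, tiny_control())
  ev <- ppi_evaluate(fit)
  key <- function(df) paste(df$protein_a, df$protein_b)
  Y <- do.call(rbind, lapply(dat$edges$labels[match(key(sp$test), key(dat$edges))],
                             function(l) ppi_labels() %in% l))
  expect_equal(ev$overall$tp + ev$overall$fn, sum(Y))
  # small random splits of a connected-ish graph rarely isolate proteins:
  # the unknown stratum may legitimately be empty and must be flagged, not 0
  if (nrow(sp$test_unknown) == 0) expect_identical(ev$unknown, "n/a")
  else expect_s3_class(ev$unknown, "ppi_metrics")
})

test_that("fitting rejects edges without sequences and empty train partitions", {
  dat <- tiny_dataset(seed = 15L)
  bad <- rbind(dat$edges[, c("protein_a", "protein_b")],
               data.frame(protein_a = "ghost", protein_b = "P001"))
  bad$labels <- I(c(dat$edges$labels, list("binding")))
  expect_error(ppi_fit(dat$proteins, bad, control = tiny_control()), "ghost")
})

test_that("model methods provide the standard interface", {
  dat <- tiny_dataset(seed = 17L)
  fit <- ppi_fit(dat$proteins, dat$edges, control = tiny_control())
  expect_output(print(fit), "multi-label PPI")
  expect_named(coef(fit), c("enc", "gin", "attn", "rel", "cls"))
  r <- residuals(fit)
  expect_equal(dim(r), c(nrow(fit$split$train), 7L))
  expect_true(all(abs(r) < 1))
  sims <- simulate(fit, nsim = 2, seed = 4L)
  expect_length(sims, 2L)
  expect_true(all(sims[[1]] %in% c(0L, 1L)))
  s <- summary(fit)
  expect_output(print(s), "Test-set performance")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("per-epoch JSONL logging works", {
  dat <- tiny_dataset(seed = 19L)
  log <- withr::local_tempfile(fileext = ".jsonl")
  fit <- ppi_fit(dat$proteins, dat$edges,
                 control = tiny_control(epochs = 2L, log_file = log))
  lines <- readLines(log)
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$epoch, 2L)
  expect_true(is.finite(rec$loss))
})
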
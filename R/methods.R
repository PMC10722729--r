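#' @export
print.ppi_fit <- function(x, ...) {
  h <- x$history
  last_f1 <- utils::tail(stats::na.omit(h$train_micro_f1), 1)
  cat("Sequence-based multi-label PPI prediction model\n")
  cat(sprintf("  proteins: %d   train edges: %d   test edges: %d (%s split, seed %d)\n",
              nrow(x$proteins), nrow(x$split$train), nrow(x$split$test),
              x$split$scheme, x$split$seed))
  comps <- c("inception"[x$control$use_inception],
             "attention"[x$control$use_attention],
             "frn"[x$control$use_frn], "ntn"[x$control$use_ntn])
  cat(sprintf("  components: %s   d_node: %d   slices: %d\n",
              paste(comps, collapse = "+"), x$arch$d_node, x$control$frn_slices))
  cat(sprintf("  epochs: %d   final loss: %.4f   train micro-F1: %s\n",
              nrow(h), h$loss[nrow(h)],
              if (length(last_f1)) sprintf("%.4f", last_f1) else "n/a"))
  invisible(x)
}

#' Summarize a fitted PPI model
#'
#' @param object A `ppi_fit`.
#' @param ... Unused.
#' @return Object of class `summary.ppi_fit`: training history tail, test
#'   metrics (overall and homologous/unknown strata) and parameter counts.
#' @export
summary.ppi_fit <- function(object, ...) {
  ev <- ppi_evaluate(object)
  n_par <- sum(unlist(rapply(object$theta, length, how = "unlist")))
  structure(list(fit = object, eval = ev, n_parameters = n_par),
            class = "summary.ppi_fit")
}

#' @export
print.summary.ppi_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  trainable parameters: %d\n", x$n_parameters))
  cat("Test-set performance:\n  overall:    ")
  print(x$eval$overall)
  cat("  homologous: ")
  if (is.character(x$eval$homologous)) cat("n/a (empty stratum)\n")
  else print(x$eval$homologous)
  cat("  unknown:    ")
  if (is.character(x$eval$unknown)) cat("n/a (empty stratum)\n")
  else print(x$eval$unknown)
  invisible(x)
}

#' @export
coef.ppi_fit <- function(object, ...) object$theta

#' @export
plot.ppi_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "summed BCE loss", main = "training loss", ...)
  keep <- !is.na(h$train_micro_f1)
  graphics::plot(h$epoch[keep], h$train_micro_f1[keep], type = "b", pch = 16,
                 cex = 0.6, ylim = c(0, 1), xlab = "epoch", ylab = "micro-F1",
                 main = "micro-F1")
  if (any(!is.na(h$test_micro_f1))) {
    kt <- !is.na(h$test_micro_f1)
    graphics::lines(h$epoch[kt], h$test_micro_f1[kt], type = "b", pch = 1,
                    cex = 0.6, lty = 2)
    graphics::legend("bottomright", c("train", "test"), lty = c(1, 2),
                     pch = c(16, 1), bty = "n")
  }
  invisible(x)
}

#' Predict interaction types for protein pairs
#'
#' @param object A fitted `ppi_fit`.
#' @param pairs data.frame with columns `protein_a`, `protein_b`; defaults
#'   to the fit's test pairs. Every id must belong to the fitted protein set.
#' @param threshold Decision cutoff (default: the fit's control threshold).
#' @param ... Unused.
#' @return data.frame in input order: `protein_a`, `protein_b`, one
#'   probability column per interaction type, and `labels` (semicolon-joined
#'   predicted label set).
#' @export
predict.ppi_fit <- function(object, pairs = object$split$test,
                            threshold = object$control$threshold, ...) {
  stopifnot(is.data.frame(pairs),
            all(c("protein_a", "protein_b") %in% names(pairs)))
  ids <- object$proteins$id
  ia <- match(pairs$protein_a, ids)
  ib <- match(pairs$protein_b, ids)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(pairs$protein_a[is.na(ia)], pairs$protein_b[is.na(ib)]))
    stop("unknown protein id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  prob <- fit_forward_pairs(object, ia, ib)
  colnames(prob) <- ppi_labels()
  sets <- apply(prob >= threshold, 1L,
                function(r) paste(ppi_labels()[r], collapse = ";"))
  out <- data.frame(protein_a = pairs$protein_a, protein_b = pairs$protein_b,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(prob), labels = sets, stringsAsFactors = FALSE)
}

#' Evaluate a fitted model on its test split
#'
#' Computes micro-F1 reports on all test edges and separately on the
#' homologous stratum (both endpoints seen in training edges) and the
#' unknown stratum (at least one unseen endpoint). Inference uses only the
#' training-graph adjacency, so unknown proteins participate with their own
#' encoder feature and whatever training neighbours they have (often none).
#'
#' @param object A `ppi_fit`.
#' @param threshold Decision cutoff (default: the fit's control threshold).
#' @return Object of class `ppi_eval`: list with `overall`, `homologous` and
#'   `unknown` — each a [micro_f1()] report, or the string `"n/a"` for an
#'   empty stratum.
#' @export
ppi_evaluate <- function(object, threshold = object$control$threshold) {
  stopifnot(inherits(object, "ppi_fit"))
  split <- object$split
  if (nrow(split$test) == 0)
    stop("the fit's split has no test edges", call. = FALSE)
  key_all <- pair_key(object$edges$protein_a, object$edges$protein_b)
  Yall <- labels_to_matrix(object$edges$labels)
  idx <- match(pair_key(split$test$protein_a, split$test$protein_b), key_all)
  if (anyNA(idx))
    stop("test pair(s) absent from the fit's edge list", call. = FALSE)
  Y <- Yall[idx, , drop = FALSE]
  ids <- object$proteins$id
  prob <- fit_forward_pairs(object, match(split$test$protein_a, ids),
                            match(split$test$protein_b, ids))
  pred <- prob >= threshold

  strat_key <- pair_key(split$test$protein_a, split$test$protein_b)
  in_hom <- strat_key %in% pair_key(split$test_homologous$protein_a,
                                    split$test_homologous$protein_b)
  sub_report <- function(sel) {
    if (!any(sel)) "n/a"
    else micro_f1(pred[sel, , drop = FALSE], Y[sel, , drop = FALSE])
  }
  structure(list(overall = micro_f1(pred, Y),
                 homologous = sub_report(in_hom),
                 unknown = sub_report(!in_hom)),
            class = "ppi_eval")
}

#' @export
print.ppi_eval <- function(x, ...) {
  cat("overall:    "); print(x$overall)
  cat("homologous: ")
  if (is.character(x$homologous)) cat("n/a (empty stratum)\n") else print(x$homologous)
  cat("unknown:    ")
  if (is.character(x$unknown)) cat("n/a (empty stratum)\n") else print(x$unknown)
  invisible(x)
}

#' Residuals of a fitted PPI model
#'
#' Raw residuals `y - p` on the training pairs, one row per pair and one
#' column per interaction type.
#'
#' @param object A `ppi_fit`.
#' @param ... Unused.
#' @return Numeric matrix (n_train_pairs x 7).
#' @export
residuals.ppi_fit <- function(object, ...) {
  ids <- object$proteins$id
  key_all <- pair_key(object$edges$protein_a, object$edges$protein_b)
  Yall <- labels_to_matrix(object$edges$labels)
  idx <- match(pair_key(object$split$train$protein_a,
                        object$split$train$protein_b), key_all)
  Y <- Yall[idx, , drop = FALSE]
  prob <- fit_forward_pairs(object, match(object$split$train$protein_a, ids),
                            match(object$split$train$protein_b, ids))
  res <- Y - prob
  colnames(res) <- ppi_labels()
  res
}

#' Simulate label sets from a fitted model
#'
#' Draws Bernoulli label indicators from the model's predicted per-type
#' probabilities for the given pairs.
#'
#' @param object A `ppi_fit`.
#' @param nsim Number of simulated label matrices.
#' @param seed Optional integer seed.
#' @param pairs Pairs to simulate for (default: the fit's test pairs).
#' @param ... Unused.
#' @return List of `nsim` binary matrices (n_pairs x 7).
#' @export
simulate.ppi_fit <- function(object, nsim = 1, seed = NULL,
                             pairs = object$split$test, ...) {
  ids <- object$proteins$id
  prob <- fit_forward_pairs(object, match(pairs$protein_a, ids),
                            match(pairs$protein_b, ids))
  draw <- function() {
    y <- matrix(stats::rbinom(length(prob), 1L, prob), nrow(prob),
                dimnames = list(NULL, ppi_labels()))
    y
  }
  if (!is.null(seed)) with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  else replicate(nsim, draw(), simplify = FALSE)
}
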
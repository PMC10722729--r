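#' Micro-averaged precision, recall and F1 over the 7 label tasks
#'
#' True/false positive and false negative counts are pooled across all
#' labels and all pairs (micro-averaging), then
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and
#' `F1 = 2 P R / (P + R)` are applied once to the pooled counts. Every label
#' decision therefore carries equal weight regardless of label frequency.
#' Zero denominators yield 0 rather than NaN.
#'
#' @param pred Binary prediction matrix (n_pairs x 7).
#' @param truth Binary ground-truth matrix of the same shape.
#' @return Object of class `ppi_metrics`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `micro_f1`, a `per_label_counts` data.frame and
#'   `macro_f1` as a supplementary summary.
#' @export
micro_f1 <- function(pred, truth) {
  pred <- rbind(pred); truth <- rbind(truth)
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have identical shape", call. = FALSE)
  pred <- pred != 0; truth <- truth != 0
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  safe_div <- function(a, b) if (b > 0) a / b else 0
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0

  lab <- if (!is.null(colnames(truth))) colnames(truth) else ppi_labels()[seq_len(ncol(truth))]
  per <- data.frame(label = lab,
                    tp = colSums(pred & truth),
                    fp = colSums(pred & !truth),
                    fn = colSums(!pred & truth),
                    row.names = NULL)
  per$f1 <- mapply(function(tp, fp, fn) {
    p <- safe_div(tp, tp + fp); r <- safe_div(tp, tp + fn)
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, per$tp, per$fp, per$fn)

  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, micro_f1 = f1,
                 per_label_counts = per, macro_f1 = mean(per$f1),
                 n_pairs = nrow(pred)),
            class = "ppi_metrics")
}

#' @export
print.ppi_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("micro-F1 %.*f  (precision %.*f, recall %.*f; TP %d, FP %d, FN %d over %d pairs)\n",
              digits, x$micro_f1, digits, x$precision, digits, x$recall,
              x$tp, x$fp, x$fn, x$n_pairs))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A `ppi_metrics` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "ppi_metrics"))
  obj <- list(precision = report$precision, recall = report$recall,
              micro_f1 = report$micro_f1,
              per_label_counts = report$per_label_counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
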
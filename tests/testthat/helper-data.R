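# Shared fixtures, built in code at test time.

tiny_dataset <- function(seed = 7L, n_proteins = 15L, n_edges = 25L,
                         length_range = c(30L, 60L), label_noise = 0) {
  simulate_ppi_data(sim_config(n_proteins = n_proteins,
                               length_range = length_range,
                               n_edges = n_edges, label_noise = label_noise,
                               seed = seed))
}

tiny_control <- function(...) {
  defaults <- list(epochs = 3L, channels = 3L, n_submodules = 2L,
                   hidden = 8L, frn_slices = 3L, learning_rate = 0.01,
                   embed_epochs = 2L, eval_every = 1L, seed = 5L)
  args <- utils::modifyList(defaults, list(...))
  do.call(ppi_control, args)
}

# edge data.frame from a compact "a-b:label1;label2" spec string vector
make_edges <- function(...) {
  specs <- c(...)
  parts <- strsplit(specs, ":", fixed = TRUE)
  pairs <- strsplit(vapply(parts, `[`, character(1), 1L), "-", fixed = TRUE)
  labels <- strsplit(vapply(parts, `[`, character(1), 2L), ";", fixed = TRUE)
  a <- vapply(pairs, `[`, character(1), 1L)
  b <- vapply(pairs, `[`, character(1), 2L)
  data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
             labels = I(labels), stringsAsFactors = FALSE)
}

random_proteins <- function(n, len = 40L, seed = 1L) {
  aa <- c("A","G","V","I","L","F","P","Y","M","T","S","H","N","Q","W","R","K","D","E","C")
  set.seed(seed)
  data.frame(id = sprintf("q%02d", seq_len(n)),
             sequence = vapply(seq_len(n), function(i)
               paste(sample(aa, len, replace = TRUE), collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

# independent micro-F1 oracle on the flattened binary vectors
flat_f1 <- function(pred, truth) {
  p <- as.logical(pred); y <- as.logical(truth)
  tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
}
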
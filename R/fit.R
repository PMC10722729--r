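#' Training control for the PPI prediction model
#'
#' Collects every tunable of the end-to-end model. The optimization defaults
#' (Adam, learning rate 0.001, batch size 2048 capped at the dataset size,
#' 300 epochs, maximum sequence length 2000, one graph layer) are the
#' standard large-scale settings for this architecture; desk-scale synthetic
#' runs typically shrink `channels`, raise `learning_rate` and cut `epochs`
#' (see the package vignette).
#'
#' @param learning_rate Adam learning rate.
#' @param lr_schedule `"constant"` (default) or `"cosine"` — cosine-anneal
#'   the learning rate to zero across the epochs, which damps the late-stage
#'   oscillation of full-batch Adam on small datasets.
#' @param batch_size Training pairs per optimization step (auto-capped at
#'   the number of training pairs).
#' @param epochs Training epochs.
#' @param max_length Maximum residues retained per sequence.
#' @param n_graph_layers GIN layers (default 1).
#' @param channels,pool_channels,n_submodules,norm Sequence-encoder
#'   architecture (see [inception_params()]).
#' @param pooling Temporal collapse of the encoder output: global average
#'   (`"mean"`, default) or global maximum (`"max"`; sharper for sparse
#'   motif-like signals).
#' @param frn_slices Tensor slices `k` of the relational scorer.
#' @param hidden Classifier hidden width.
#' @param threshold Per-label decision cutoff for predicted label sets.
#' @param use_inception,use_attention,use_frn,use_ntn Ablation switches.
#'   Disabling the encoder falls back to mean-pooled residue embeddings with
#'   a linear map; disabling attention passes graph features through
#'   unchanged; `use_ntn` swaps the relational scorer for the NTN bilinear
#'   form (at most one of `use_frn`/`use_ntn`).
#' @param fusion What feeds the classifier: `"concat"` (relational k-vector
#'   concatenated with the elementwise product of the pair features),
#'   `"relational"` (k-vector only) or `"product"` (elementwise product only).
#' @param scale_attention Apply the `1/sqrt(d_k)` attention scaling.
#' @param embed_window,embed_negatives,embed_epochs,embed_mode,embed_corpus
#'   Skip-gram subembedding settings; `embed_corpus = "train"` (default)
#'   restricts the corpus to proteins seen in training edges, avoiding
#'   leakage into unknown-protein evaluation; `"all"` uses every sequence.
#' @param eval_every Record train/test micro-F1 every this many epochs
#'   (1 = every epoch; other epochs hold NA in the history).
#' @param log_file Optional path receiving one JSON line per epoch.
#' @param seed Integer seed governing all randomness of the fit.
#' @param verbose Print per-epoch progress to stderr.
#' @return Object of class `ppi_control`.
#' @export
ppi_control <- function(learning_rate = 0.001,
                        lr_schedule = c("constant", "cosine"),
                        batch_size = 2048L,
                        epochs = 300L, max_length = 2000L,
                        n_graph_layers = 1L, channels = 32L,
                        pool_channels = channels, n_submodules = 4L,
                        norm = TRUE, pooling = c("mean", "max"),
                        frn_slices = 8L, hidden = 32L,
                        threshold = 0.5, use_inception = TRUE,
                        use_attention = TRUE, use_frn = TRUE,
                        use_ntn = FALSE,
                        fusion = c("concat", "relational", "product"),
                        scale_attention = TRUE, embed_window = 1L,
                        embed_negatives = 5L, embed_epochs = 5L,
                        embed_mode = c("residue", "kmer"),
                        embed_corpus = c("train", "all"), eval_every = 10L,
                        log_file = NULL, seed = 1L, verbose = FALSE) {
  fusion <- match.arg(fusion)
  lr_schedule <- match.arg(lr_schedule)
  pooling <- match.arg(pooling)
  embed_mode <- match.arg(embed_mode)
  embed_corpus <- match.arg(embed_corpus)
  if (use_frn && use_ntn)
    stop("use_frn and use_ntn are mutually exclusive", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "ppi_control")
}

# resolve derived dimensions and flags from a control object
model_arch <- function(control) {
  d_node <- 3L * control$channels + control$pool_channels
  d_pair <- d_node  # attention maps d_node -> d_k = d_node
  relational <- control$use_frn || control$use_ntn
  d_fused <- if (!relational) d_pair
  else switch(control$fusion,
              concat = control$frn_slices + d_pair,
              relational = control$frn_slices,
              product = d_pair)
  list(d_node = d_node, d_pair = d_pair, d_fused = d_fused,
       relational = relational, ntn = control$use_ntn,
       n_labels = length(ppi_labels()))
}

init_theta <- function(control, arch) {
  s <- control$seed
  theta <- list()
  theta$enc <- if (control$use_inception) {
    inception_params(13L, control$channels, control$pool_channels,
                     control$n_submodules, control$norm, seed = s + 1L)$blocks
  } else {
    with_seed(s + 1L, list(W = glorot(13L, arch$d_node), b = numeric(arch$d_node)))
  }
  theta$gin <- lapply(seq_len(control$n_graph_layers), function(i)
    unclass(gin_params(arch$d_node, seed = s + 1L + i)))
  if (control$use_attention)
    theta$attn <- unclass(attention_params(arch$d_node, arch$d_pair,
                                           control$scale_attention,
                                           seed = s + 10L))[c("Wq", "Wk", "Wv")]
  if (arch$relational)
    theta$rel <- unclass(frn_params(arch$d_pair, control$frn_slices,
                                    seed = s + 11L))
  theta$cls <- unclass(classifier_params(arch$d_fused, control$hidden,
                                         seed = s + 12L))
  theta
}

# full-model forward over a set of pair indices; returns caches for backward.
# arch$calib, when present, is a fixed affine (center, scale) applied to the
# pooled encoder features: computed once at initialization so node features
# start standardized across the training proteins, it is part of the model
# constants, not a trained or batch-dependent statistic.
model_fwd <- function(theta, control, arch, Xlist, A, ia, ib, want_cache = TRUE) {
  n <- length(Xlist)
  Z <- matrix(0, n, arch$d_node)
  enc_caches <- if (want_cache) vector("list", n) else NULL
  if (control$use_inception) {
    ip <- structure(list(blocks = theta$enc, c_in = 13L,
                         channels = control$channels,
                         pool_channels = control$pool_channels,
                         n_submodules = control$n_submodules,
                         norm = control$norm, d_node = arch$d_node),
                    class = "inception_params")
    for (i in seq_len(n)) {
      f <- encoder_fwd(Xlist[[i]], ip, control$pooling)
      Z[i, ] <- f$z
      if (want_cache) enc_caches[[i]] <- f
    }
  } else {
    Xbar <- t(vapply(Xlist, rowMeans, numeric(13L)))
    Z <- linear_fwd(Xbar, theta$enc$W, theta$enc$b)
    if (want_cache) enc_caches <- Xbar
  }
  if (!is.null(arch$calib))
    Z <- sweep(Z, 2L, arch$calib$center, "-") *
      matrix(arch$calib$scale, nrow(Z), ncol(Z), byrow = TRUE)
  H <- Z
  gin_caches <- if (want_cache) vector("list", length(theta$gin)) else NULL
  gin_inputs <- if (want_cache) vector("list", length(theta$gin)) else NULL
  for (l in seq_along(theta$gin)) {
    if (want_cache) gin_inputs[[l]] <- H
    g <- gin_fwd(H, A, theta$gin[[l]])
    if (want_cache) gin_caches[[l]] <- g
    H <- g$H
  }
  P1 <- H[ia, , drop = FALSE]
  P2 <- H[ib, , drop = FALSE]
  if (control$use_attention) {
    at <- attn_pair_fwd(P1, P2, c(theta$attn, list(scale = control$scale_attention)))
    E1 <- at$O1; E2 <- at$O2
  } else {
    at <- NULL
    E1 <- P1; E2 <- P2
  }
  if (arch$relational) {
    rel <- relational_fwd(E1, E2, theta$rel, ntn = arch$ntn)
    U <- switch(control$fusion,
                concat = cbind(rel$Fk, E1 * E2),
                relational = rel$Fk,
                product = E1 * E2)
  } else {
    rel <- NULL
    U <- E1 * E2
  }
  cl <- classifier_fwd(U, theta$cls)
  list(prob = cl$prob, Z = Z, H = H, E1 = E1, E2 = E2, U = U,
       enc_caches = enc_caches, gin_caches = gin_caches,
       gin_inputs = gin_inputs, at = at, rel = rel, cl = cl,
       P1 = P1, P2 = P2)
}

model_bwd <- function(theta, control, arch, Xlist, A, ia, ib, fw, Y) {
  m <- length(ia)
  grads <- zeros_like(theta)
  dlogits <- fw$prob - Y  # gradient of summed BCE through the sigmoid
  cb <- classifier_bwd(dlogits, fw$U, theta$cls, fw$cl)
  grads$cls <- cb$grads
  dU <- cb$dU

  d <- arch$d_pair
  if (arch$relational) {
    k <- control$frn_slices
    dF <- switch(control$fusion,
                 concat = dU[, seq_len(k), drop = FALSE],
                 relational = dU,
                 product = matrix(0, m, k))
    dProd <- switch(control$fusion,
                    concat = dU[, k + seq_len(d), drop = FALSE],
                    relational = matrix(0, m, d),
                    product = dU)
    rb <- relational_bwd(dF, fw$E1, fw$E2, theta$rel, fw$rel)
    grads$rel <- rb$grads
    dE1 <- rb$dE1 + dProd * fw$E2
    dE2 <- rb$dE2 + dProd * fw$E1
  } else {
    dE1 <- dU * fw$E2
    dE2 <- dU * fw$E1
  }

  if (control$use_attention) {
    ab <- attn_pair_bwd(dE1, dE2, fw$P1, fw$P2,
                        c(theta$attn, list(scale = control$scale_attention)), fw$at)
    grads$attn <- ab$grads
    dP1 <- ab$dE1; dP2 <- ab$dE2
  } else {
    dP1 <- dE1; dP2 <- dE2
  }

  # scatter pair gradients back onto graph nodes
  n <- length(Xlist)
  dH <- matrix(0, n, arch$d_node)
  agg <- rowsum(rbind(dP1, dP2), group = c(ia, ib))
  dH[as.integer(rownames(agg)), ] <- agg

  for (l in rev(seq_along(theta$gin))) {
    gb <- gin_bwd(dH, fw$gin_inputs[[l]], A, theta$gin[[l]], fw$gin_caches[[l]])
    grads$gin[[l]] <- gb$grads
    dH <- gb$dZ
  }
  dZ <- dH
  if (!is.null(arch$calib))
    dZ <- dZ * matrix(arch$calib$scale, nrow(dZ), ncol(dZ), byrow = TRUE)

  if (control$use_inception) {
    ip <- structure(list(blocks = theta$enc, c_in = 13L,
                         channels = control$channels,
                         pool_channels = control$pool_channels,
                         n_submodules = control$n_submodules,
                         norm = control$norm, d_node = arch$d_node),
                    class = "inception_params")
    enc_g <- NULL
    for (i in seq_len(n)) {
      if (all(dZ[i, ] == 0)) next
      g <- encoder_bwd(dZ[i, ], ip, fw$enc_caches[[i]])
      enc_g <- add_grads(enc_g, g)
    }
    if (!is.null(enc_g)) grads$enc <- enc_g
  } else {
    lb <- linear_bwd(dZ, fw$enc_caches, theta$enc$W)
    grads$enc <- list(W = lb$dW, b = lb$db)
  }
  grads
}

#' Fit the sequence-based multi-label PPI prediction model
#'
#' End-to-end training: residue skip-gram embedding, Inception sequence
#' encoder, GIN propagation over the training interaction graph,
#' self-attention pair refinement, relational scoring and the 7-way
#' multi-label classifier, optimized jointly with Adam on the summed
#' multi-task binary cross-entropy. The interaction graph is built from the
#' training partition only; test edges never enter the adjacency, so
#' evaluation on BFS/DFS splits is genuinely inductive.
#'
#' @param proteins data.frame (`id`, `sequence`) covering every edge endpoint.
#' @param edges Edge data.frame (`protein_a`, `protein_b`, list-column
#'   `labels`) of ground-truth interactions.
#' @param split A `ppi_split` from [random_split()]/[traversal_split()];
#'   default: a random 80/20 split under the control seed.
#' @param control A [ppi_control()] object.
#' @return Object of class `ppi_fit` with the trained parameters, the
#'   embedding vocabulary, the split, and a per-epoch `history` data.frame
#'   (`epoch`, `loss`, `train_micro_f1`, `test_micro_f1`).
#' @seealso [ppi_evaluate()], [predict.ppi_fit()]
#' @export
ppi_fit <- function(proteins, edges, split = NULL, control = ppi_control()) {
  stopifnot(inherits(control, "ppi_control"))
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  ep <- unique(c(edges$protein_a, edges$protein_b))
  missing <- setdiff(ep, proteins$id)
  if (length(missing) > 0)
    stop("edge endpoint(s) without a sequence: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(split)) split <- random_split(edges, 0.2, seed = control$seed)
  stopifnot(inherits(split, "ppi_split"))
  if (nrow(split$train) == 0) stop("training partition is empty", call. = FALSE)

  # ground-truth label matrices keyed by unordered pair
  key_all <- pair_key(edges$protein_a, edges$protein_b)
  Yall <- labels_to_matrix(edges$labels)
  lookup_Y <- function(pairs, strict = TRUE) {
    idx <- match(pair_key(pairs$protein_a, pairs$protein_b), key_all)
    if (anyNA(idx)) {
      if (strict)
        stop("split contains pair(s) absent from the edge list", call. = FALSE)
      return(NULL)  # labels unavailable (e.g. held-out test edges removed)
    }
    Yall[idx, , drop = FALSE]
  }
  Ytrain <- lookup_Y(split$train)
  Ytest <- if (nrow(split$test) > 0) lookup_Y(split$test, strict = FALSE) else NULL

  # skip-gram corpus: training-graph proteins by default (no test leakage)
  corpus_ids <- if (control$embed_corpus == "train")
    unique(c(split$train$protein_a, split$train$protein_b)) else proteins$id
  vocab <- train_cooccurrence(proteins[proteins$id %in% corpus_ids, , drop = FALSE],
                              dim = 5L, window = control$embed_window,
                              negatives = control$embed_negatives,
                              epochs = control$embed_epochs,
                              mode = control$embed_mode, seed = control$seed)
  classes <- aa_class_map()
  Xlist <- lapply(seq_len(nrow(proteins)), function(i)
    encode_sequence(proteins[i, ], vocab, classes, control$max_length))

  arch <- model_arch(control)
  theta <- init_theta(control, arch)
  # start the output bias at the empirical base-rate logits so the sparse
  # multi-label head begins calibrated instead of descending there first
  base <- pmin(pmax(colMeans(Ytrain), 0.01), 0.99)
  theta$cls$b2 <- stats::qlogis(base)

  # data-dependent initialization of the node-feature scale: a fixed affine
  # standardizing the pooled encoder outputs across the training-graph
  # proteins (computed once from the initial weights, never updated, and
  # free of test information). Without it the random encoder's pooled
  # features share a large common mode and optimization crawls.
  train_ids <- unique(c(split$train$protein_a, split$train$protein_b))
  tr_idx <- match(train_ids, proteins$id)
  Z0 <- model_fwd(theta, control, arch, Xlist,
                  matrix(0, nrow(proteins), nrow(proteins)),
                  tr_idx[1], tr_idx[1], want_cache = FALSE)$Z[tr_idx, , drop = FALSE]
  arch$calib <- list(center = colMeans(Z0),
                     scale = 1 / pmax(apply(Z0, 2L, stats::sd), 1e-6))
  graph0 <- build_ppi_graph(proteins, matrix(0, nrow(proteins), arch$d_node),
                            split$train)
  A <- graph0$adjacency

  ia <- match(split$train$protein_a, proteins$id)
  ib <- match(split$train$protein_b, proteins$id)
  ia_te <- match(split$test$protein_a, proteins$id)
  ib_te <- match(split$test$protein_b, proteins$id)

  m <- length(ia)
  bs <- min(control$batch_size, m)
  state <- adam_init(theta)
  hist <- data.frame(epoch = seq_len(control$epochs), loss = NA_real_,
                     train_micro_f1 = NA_real_, test_micro_f1 = NA_real_)
  log_con <- if (!is.null(control$log_file)) file(control$log_file, "w")
  if (!is.null(log_con)) on.exit(close(log_con), add = TRUE)

  with_seed(control$seed + 100L, {
    for (epoch in seq_len(control$epochs)) {
      lr_now <- if (control$lr_schedule == "cosine")
        control$learning_rate * 0.5 * (1 + cos(pi * (epoch - 1) / control$epochs))
      else control$learning_rate
      ord <- sample.int(m)
      total <- 0
      for (start in seq(1L, m, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, m)]
        fw <- model_fwd(theta, control, arch, Xlist, A, ia[idx], ib[idx])
        loss <- bce_multilabel_loss(fw$prob, Ytrain[idx, , drop = FALSE])
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch,
               " (diverged; lower the learning rate)", call. = FALSE)
        total <- total + loss
        grads <- model_bwd(theta, control, arch, Xlist, A, ia[idx], ib[idx],
                           fw, Ytrain[idx, , drop = FALSE])
        upd <- adam_step(theta, grads, state, lr_now)
        theta <- upd$params
        state <- upd$state
      }
      hist$loss[epoch] <- total
      if (epoch %% control$eval_every == 0 || epoch == control$epochs) {
        ftr <- model_fwd(theta, control, arch, Xlist, A, ia, ib, want_cache = FALSE)
        hist$train_micro_f1[epoch] <-
          micro_f1(ftr$prob >= control$threshold, Ytrain)$micro_f1
        if (!is.null(Ytest) && length(ia_te) > 0) {
          fte <- model_fwd(theta, control, arch, Xlist, A, ia_te, ib_te,
                           want_cache = FALSE)
          hist$test_micro_f1[epoch] <-
            micro_f1(fte$prob >= control$threshold, Ytest)$micro_f1
        }
      }
      if (control$verbose)
        message(sprintf("epoch %d  loss %.4f  train_f1 %s  test_f1 %s",
                        epoch, total,
                        format(hist$train_micro_f1[epoch], digits = 4),
                        format(hist$test_micro_f1[epoch], digits = 4)))
      if (!is.null(log_con))
        writeLines(jsonlite::toJSON(
          list(epoch = epoch, loss = total,
               train_micro_f1 = hist$train_micro_f1[epoch],
               test_micro_f1 = hist$test_micro_f1[epoch]),
          auto_unbox = TRUE, na = "null", digits = NA), log_con)
    }
  })

  structure(list(theta = theta, arch = arch, control = control,
                 vocab = vocab, classes = classes,
                 proteins = proteins, split = split, edges = edges,
                 adjacency = A, history = hist, call = match.call()),
            class = "ppi_fit")
}

# forward pass for arbitrary pairs with the fitted parameters
fit_forward_pairs <- function(object, ia, ib) {
  Xlist <- lapply(seq_len(nrow(object$proteins)), function(i)
    encode_sequence(object$proteins[i, ], object$vocab, object$classes,
                    object$control$max_length))
  model_fwd(object$theta, object$control, object$arch, Xlist,
            object$adjacency, ia, ib, want_cache = FALSE)$prob
}
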
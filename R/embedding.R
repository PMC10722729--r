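#' Train the residue co-occurrence subembedding (skip-gram)
#'
#' Learns a low-dimensional co-occurrence embedding of amino acids with the
#' skip-gram objective and negative sampling, trained on the corpus of
#' protein sequences. Two tokenizations are supported:
#' \describe{
#'   \item{`"residue"` (default)}{tokens are single residues with a context
#'     window of 1 on each side, so each centre token's context is exactly
#'     its overlapping 3-mer; this yields one vector per residue directly.}
#'   \item{`"kmer"`}{tokens are overlapping 3-mers; at encoding time a
#'     residue's vector is the average of the (up to three) 3-mer vectors
#'     covering its position.}
#' }
#' Tokens absent from the training corpus map to the zero vector, so unseen
#' proteins remain encodable at inference time.
#'
#' @param proteins data.frame with columns `id`, `sequence` (see
#'   [read_fasta()]), or a character vector of sequences.
#' @param dim Embedding dimension; the model's residue encoding assumes 5.
#'   Other values are accepted but flagged with a message.
#' @param window Context window half-width (tokens on each side).
#' @param negatives Number of negative samples per positive pair.
#' @param epochs Passes over the corpus.
#' @param lr Initial learning rate (decays linearly to a tenth across
#'   training).
#' @param mode Tokenization, `"residue"` or `"kmer"`.
#' @param seed Integer seed; identical seed and corpus give identical vectors.
#' @return An object of class `ppi_vocab`: list with `vectors` (token-by-dim
#'   matrix), `dim`, `mode`, and `training_meta` (window, negatives, epochs,
#'   lr, seed).
#' @export
train_cooccurrence <- function(proteins, dim = 5L, window = 1L, negatives = 5L,
                               epochs = 5L, lr = 0.05, mode = c("residue", "kmer"),
                               seed = 1L) {
  mode <- match.arg(mode)
  seqs <- if (is.data.frame(proteins)) proteins$sequence else as.character(proteins)
  seqs <- toupper(seqs[nchar(seqs) >= 3L])
  if (length(seqs) == 0)
    stop("embedding corpus is empty (no sequence of length >= 3)", call. = FALSE)
  if (dim != 5L)
    message("note: co-occurrence dimension ", dim,
            " deviates from the standard 5-dimensional subembedding")

  token_streams <- lapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (mode == "residue") ch
    else vapply(seq_len(length(ch) - 2L),
                function(i) paste(ch[i:(i + 2L)], collapse = ""), character(1))
  })
  counts <- table(unlist(token_streams))
  vocab <- names(counts)
  nv <- length(vocab)
  stream_idx <- lapply(token_streams, function(s) match(s, vocab))

  # unigram^{3/4} table for negative sampling
  neg_prob <- as.numeric(counts)^0.75
  neg_prob <- neg_prob / sum(neg_prob)

  n_pos_total <- sum(vapply(stream_idx, function(s) {
    L <- length(s)
    sum(pmin(seq_len(L) - 1L, window) + pmin(L - seq_len(L), window))
  }, numeric(1))) * epochs

  with_seed(seed, {
    W <- matrix(stats::runif(nv * dim, -0.5, 0.5) / dim, nrow = nv)
    C <- matrix(0, nrow = nv, ncol = dim)
    step <- 0
    for (ep in seq_len(epochs)) {
      for (s in stream_idx) {
        L <- length(s)
        for (t in seq_len(L)) {
          lo <- max(1L, t - window); hi <- min(L, t + window)
          ctx <- s[setdiff(lo:hi, t)]
          for (cx in ctx) {
            step <- step + 1
            eta <- lr * max(0.1, 1 - step / n_pos_total)
            targets <- c(cx, sample.int(nv, negatives, replace = TRUE,
                                        prob = neg_prob))
            lab <- c(1, numeric(negatives))
            w <- W[s[t], ]
            sc <- drop(C[targets, , drop = FALSE] %*% w)
            g <- eta * (lab - 1 / (1 + exp(-sc)))
            W[s[t], ] <- w + drop(crossprod(C[targets, , drop = FALSE], g))
            C[targets, ] <- C[targets, , drop = FALSE] + outer(g, w)
          }
        }
      }
    }
  })
  rownames(W) <- vocab
  structure(list(vectors = W, dim = as.integer(dim), mode = mode,
                 training_meta = list(window = as.integer(window),
                                      negatives = as.integer(negatives),
                                      epochs = as.integer(epochs),
                                      lr = lr, seed = as.integer(seed))),
            class = "ppi_vocab")
}

#' @export
print.ppi_vocab <- function(x, ...) {
  cat(sprintf("residue co-occurrence embedding: %d tokens x %d dims (%s mode)\n",
              nrow(x$vectors), x$dim, x$mode))
  invisible(x)
}

#' Save / load a co-occurrence vocabulary as JSON
#'
#' @param vocab A `ppi_vocab` object.
#' @param path JSON path.
#' @return `write_vocab` returns `path` invisibly; `read_vocab` a `ppi_vocab`.
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "ppi_vocab"))
  obj <- list(dim = vocab$dim, mode = vocab$mode,
              training_meta = vocab$training_meta,
              token_vectors = stats::setNames(
                lapply(seq_len(nrow(vocab$vectors)),
                       function(i) unname(vocab$vectors[i, ])),
                rownames(vocab$vectors)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- do.call(rbind, obj$token_vectors)
  structure(list(vectors = W, dim = as.integer(obj$dim), mode = obj$mode,
                 training_meta = obj$training_meta),
            class = "ppi_vocab")
}

# per-token embedding lookup for one sequence -> matrix (dim x L)
cooc_lookup <- function(chars, vocab) {
  d <- vocab$dim
  L <- length(chars)
  if (vocab$mode == "residue") {
    idx <- match(chars, rownames(vocab$vectors))
    M <- matrix(0, nrow = d, ncol = L)
    ok <- !is.na(idx)
    if (any(ok)) M[, ok] <- t(vocab$vectors[idx[ok], , drop = FALSE])
    return(M)
  }
  # kmer mode: average the <=3 overlapping 3-mer vectors covering a position
  M <- matrix(0, nrow = d, ncol = L)
  if (L < 3L) return(M)
  kmers <- vapply(seq_len(L - 2L),
                  function(i) paste(chars[i:(i + 2L)], collapse = ""), character(1))
  kidx <- match(kmers, rownames(vocab$vectors))
  K <- matrix(0, nrow = d, ncol = L - 2L)
  ok <- !is.na(kidx)
  if (any(ok)) K[, ok] <- t(vocab$vectors[kidx[ok], , drop = FALSE])
  for (j in seq_len(L)) {
    cov <- max(1L, j - 2L):min(j, L - 2L)
    M[, j] <- rowMeans(K[, cov, drop = FALSE])
  }
  M
}

#' Encode a protein sequence as a residue feature matrix
#'
#' Builds the 13-row residue matrix consumed by the sequence encoder: for
#' each residue, the concatenation of its 5-dimensional co-occurrence vector
#' (zero for tokens unseen in training) and an 8-way one-hot of its
#' physicochemical class (7 canonical classes, plus the catch-all class for
#' U, O and unknown letters). Sequences longer than `max_length` are
#' truncated from the right.
#'
#' @param protein A one-row data.frame (`id`, `sequence`) or a character
#'   sequence.
#' @param vocab A `ppi_vocab` from [train_cooccurrence()].
#' @param classes Class map from [aa_class_map()].
#' @param max_length Maximum sequence length retained (default 2000).
#' @return Numeric matrix with `5 + 8 = 13` rows and `min(L, max_length)`
#'   columns; attribute `protein_id` carries the id when supplied.
#' @export
encode_sequence <- function(protein, vocab, classes = aa_class_map(),
                            max_length = 2000L) {
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L)
    id <- protein$id
    seqstr <- protein$sequence
  } else {
    id <- NULL
    seqstr <- as.character(protein)
  }
  seqstr <- toupper(seqstr)
  if (!nzchar(seqstr)) stop("cannot encode an empty sequence", call. = FALSE)
  chars <- strsplit(seqstr, "")[[1]]
  if (length(chars) > max_length) chars <- chars[seq_len(max_length)]
  L <- length(chars)

  cls <- classes[chars]
  cls[is.na(cls)] <- 8L  # anything outside A-Z
  onehot <- matrix(0, nrow = 8L, ncol = L)
  onehot[cbind(cls, seq_len(L))] <- 1

  X <- rbind(cooc_lookup(chars, vocab), onehot)
  rownames(X) <- c(paste0("cooc", 1:5), paste0("class", 1:8))
  if (!is.null(id)) attr(X, "protein_id") <- id
  X
}
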
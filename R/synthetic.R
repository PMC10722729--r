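#' Configuration for the synthetic PPI network generator
#'
#' Describes a STRING-like multi-label PPI benchmark small enough to train
#' on a desktop: random protein sequences over the 20-letter alphabet (with
#' occasional U/X letters), a hub-skewed undirected edge set, and per-edge
#' label subsets of the 7 interaction types driven by sequence content. Each
#' interaction type is tied to a short sequence motif; an edge carries type
#' `t` exactly when both endpoint proteins contain motif `t`, so the
#' sequence-to-label mapping is learnable by a sequence encoder (and, with
#' `label_noise = 0`, deterministic).
#'
#' @param n_proteins Number of proteins (default 50).
#' @param length_range Integer (min, max) sequence length (default 50-200).
#' @param n_edges Number of distinct undirected edges (default 150).
#' @param motif_table Named character vector mapping each of the 7
#'   interaction types to a distinct non-empty motif (defaults to built-in
#'   5-mers).
#' @param motif_copies Copies of each planted motif per carrier protein
#'   (default 2; repeated occurrences strengthen the pooled sequence signal,
#'   as functional motifs commonly recur).
#' @param label_noise Probability of flipping each of an edge's 7 label
#'   indicators (default 0 = noise-free).
#' @param unknown_rate Per-position probability of replacing a canonical
#'   residue with U or X (default 0.001).
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 50L, length_range = c(50L, 200L),
                       n_edges = 150L, motif_table = default_motifs(),
                       motif_copies = 2L, label_noise = 0,
                       unknown_rate = 0.001, seed = 1L) {
  if (length(length_range) != 2L || length_range[1] < 10L ||
      length_range[1] > length_range[2])
    stop("length_range must be (min, max) with 10 <= min <= max", call. = FALSE)
  if (n_edges > n_proteins * (n_proteins - 1) / 2)
    stop("n_edges exceeds the number of possible pairs", call. = FALSE)
  motif_table <- motif_table[ppi_labels()]
  if (anyNA(motif_table) || any(!nzchar(motif_table)) ||
      anyDuplicated(motif_table) > 0)
    stop("motif_table must assign a distinct non-empty motif to each of the 7 types",
         call. = FALSE)
  if (label_noise < 0 || label_noise >= 1)
    stop("label_noise must be in [0, 1)", call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_edges = as.integer(n_edges),
                 motif_table = motif_table,
                 motif_copies = as.integer(motif_copies),
                 label_noise = label_noise,
                 unknown_rate = unknown_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Built-in motif table
#'
#' Seven distinct 5-mers, one per interaction type. At 5 residues a motif
#' fits inside the largest convolution kernel of the sequence encoder, and a
#' chance occurrence in uniform background sequence is vanishingly rare
#' (20^-5 per position).
#'
#' @return Named character vector over [ppi_labels()].
#' @export
default_motifs <- function() {
  c(activation = "ADKEW", binding = "CYWHC", catalysis = "HEMHM",
    expression = "PWFPN", inhibition = "YGICG", ptmod = "WRSRD",
    reaction = "MKCQC")
}

#' Generate synthetic protein sequences with planted motifs
#'
#' Each protein gets a uniform random sequence over the 20 canonical
#' residues (positions swapped to U or X at `unknown_rate`), then carries
#' 0-3 interaction-type motifs, each written into the sequence
#' `motif_copies` times at random positions. Because later plants may
#' overwrite earlier ones, ground-truth motif content is always re-derived
#' from the final sequence, never from the planting plan.
#'
#' @param cfg A `sim_config`.
#' @return data.frame with columns `id`, `sequence` (ids `P001`, `P002`, ...).
#' @export
gen_proteins <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  aa <- canonical_residues()
  with_seed(cfg$seed, {
    lens <- sample(cfg$length_range[1]:cfg$length_range[2], cfg$n_proteins,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      ch <- sample(aa, L, replace = TRUE)
      odd <- stats::runif(L) < cfg$unknown_rate
      if (any(odd)) ch[odd] <- sample(c("U", "X"), sum(odd), replace = TRUE)
      n_motifs <- sample(0:3, 1L)
      if (n_motifs > 0) {
        for (m in sample(cfg$motif_table, n_motifs)) {
          w <- nchar(m)
          for (r in seq_len(cfg$motif_copies)) {
            at <- sample.int(L - w + 1L, 1L)
            ch[at:(at + w - 1L)] <- strsplit(m, "")[[1]]
          }
        }
      }
      paste(ch, collapse = "")
    }, character(1))
    data.frame(id = sprintf("P%03d", seq_len(cfg$n_proteins)),
               sequence = seqs, stringsAsFactors = FALSE)
  })
}

# n_proteins x 7 logical matrix: does protein i contain motif for type t
motif_content <- function(proteins, motif_table) {
  sapply(motif_table, function(m) grepl(m, proteins$sequence, fixed = TRUE))
}

#' Generate a synthetic multi-label interaction network
#'
#' Edges are sampled by preferential attachment (endpoint weight
#' `degree + 1`), producing the right-skewed, hub-dominated degree
#' distribution typical of PPI networks — which in turn makes BFS/DFS
#' traversal splits behave very differently from random splits. An edge's
#' label set is `{t : both endpoints contain motif t}`, with one random
#' fallback label when the intersection is empty (ground-truth edges always
#' carry at least one type); each label indicator is then flipped with
#' probability `label_noise`.
#'
#' @param proteins Output of [gen_proteins()].
#' @param cfg The same `sim_config`.
#' @return Edge data.frame (`protein_a`, `protein_b`, list-column `labels`).
#' @export
gen_network <- function(proteins, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(proteins)
  if (cfg$n_edges > n * (n - 1) / 2)
    stop("n_edges exceeds the number of possible pairs", call. = FALSE)
  content <- motif_content(proteins, cfg$motif_table)
  lab <- ppi_labels()
  with_seed(cfg$seed + 1L, {
    deg <- rep(0, n)
    seen <- character(0)
    ia <- integer(cfg$n_edges); ib <- integer(cfg$n_edges)
    for (e in seq_len(cfg$n_edges)) {
      repeat {
        a <- sample.int(n, 1L, prob = deg + 1)
        b <- sample.int(n, 1L, prob = deg + 1)
        if (a == b) next
        key <- paste(min(a, b), max(a, b))
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      ia[e] <- min(a, b); ib[e] <- max(a, b)
      deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
    }
    labels <- lapply(seq_len(cfg$n_edges), function(e) {
      y <- content[ia[e], ] & content[ib[e], ]
      if (!any(y)) y[sample.int(length(lab), 1L)] <- TRUE
      if (cfg$label_noise > 0) {
        flip <- stats::runif(length(lab)) < cfg$label_noise
        y <- xor(y, flip)
        if (!any(y)) y[sample.int(length(lab), 1L)] <- TRUE
      }
      lab[y]
    })
    data.frame(protein_a = proteins$id[ia], protein_b = proteins$id[ib],
               labels = I(labels), stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [gen_proteins()] then [gen_network()].
#'
#' @param cfg A `sim_config` (default `sim_config()`).
#' @return List with `proteins`, `edges` and `config`.
#' @export
simulate_ppi_data <- function(cfg = sim_config()) {
  proteins <- gen_proteins(cfg)
  list(proteins = proteins, edges = gen_network(proteins, cfg), config = cfg)
}
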
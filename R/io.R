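#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased on read; characters outside the canonical
#' alphabet are retained (the embedding stage maps them to the catch-all
#' class rather than dropping them). The record id is the first
#' whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, one row per record,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA header ('>') found in ", path, call. = FALSE)
  if (any(nzchar(trimws(lines[seq_len(hdr[1] - 1)]))))
    stop("malformed FASTA: sequence data before first header at line ",
         which(nzchar(trimws(lines)))[1], call. = FALSE)
  # name the offending line for empty records before handing off to Biostrings
  ends <- c(hdr[-1] - 1L, length(lines))
  for (i in seq_along(hdr)) {
    body <- lines[setdiff(seq(hdr[i], ends[i]), hdr[i])]
    if (sum(nchar(gsub("\\s", "", body))) == 0)
      stop("empty sequence for FASTA record at line ", hdr[i], call. = FALSE)
    if (!nzchar(trimws(sub("^>", "", lines[hdr[i]]))))
      stop("malformed FASTA header at line ", hdr[i], call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate protein id(s) in FASTA: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  data.frame(id = ids,
             sequence = toupper(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins data.frame with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# unordered pair key, for merging and set operations on edges
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Read a multi-label interaction edge list
#'
#' Reads a STRING-actions-style TSV with header columns `protein_a`,
#' `protein_b`, `mode` — one row per (pair, interaction type). Rows for the
#' same unordered pair are merged (label union); the long spelling
#' "post-translational modification" is accepted for `ptmod`.
#'
#' @param path Path to the TSV.
#' @return Edge data.frame with columns `protein_a`, `protein_b` and a
#'   list-column `labels` of character vectors, one row per unordered pair in
#'   first-appearance order.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("edge file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("protein_a", "protein_b", "mode")
  if (!all(need %in% names(tab)))
    stop("edge TSV must have header columns protein_a, protein_b, mode",
         call. = FALSE)
  if (any(tab$protein_a == tab$protein_b)) {
    bad <- which(tab$protein_a == tab$protein_b)[1]
    stop("self-interaction not allowed (row ", bad, ": ",
         tab$protein_a[bad], ")", call. = FALSE)
  }
  tab$mode <- canonical_label(tab$mode)
  key <- pair_key(tab$protein_a, tab$protein_b)
  first <- !duplicated(key)
  ord <- key[first]
  labels <- lapply(split(tab$mode, factor(key, levels = ord)),
                   function(x) sort(unique(x)))
  data.frame(protein_a = pmin(tab$protein_a, tab$protein_b)[first],
             protein_b = pmax(tab$protein_a, tab$protein_b)[first],
             labels = I(unname(labels[ord])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a multi-label interaction edge list
#'
#' Inverse of [read_edges()]: expands each edge back to one row per label.
#'
#' @param edges Edge data.frame (`protein_a`, `protein_b`, `labels`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  n <- lengths(edges$labels)
  out <- data.frame(protein_a = rep(edges$protein_a, n),
                    protein_b = rep(edges$protein_b, n),
                    mode = unlist(edges$labels),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_ppi_split <- function(scheme, seed, train, test) {
  strat <- stratify_test(train, test)
  structure(list(scheme = scheme, seed = as.integer(seed),
                 train = train, test = test,
                 test_homologous = strat$test_homologous,
                 test_unknown = strat$test_unknown),
            class = "ppi_split")
}

#' @export
print.ppi_split <- function(x, ...) {
  cat(sprintf("PPI edge split  scheme=%s  seed=%d\n", x$scheme, x$seed))
  cat(sprintf("  train: %d edges\n  test:  %d edges (%d homologous, %d unknown)\n",
              nrow(x$train), nrow(x$test),
              nrow(x$test_homologous), nrow(x$test_unknown)))
  invisible(x)
}

#' Write a train/test edge split to a TSV file
#'
#' The file carries a `# scheme=<scheme> seed=<seed>` comment line followed by
#' a TSV with columns `protein_a`, `protein_b`, `partition` (train/test).
#' Homologous/unknown strata are not stored; they are recomputed on read.
#'
#' @param split A `ppi_split` object (see [random_split()], [traversal_split()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "ppi_split"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scheme=%s seed=%d", split$scheme, split$seed), con)
  tab <- rbind(
    data.frame(protein_a = split$train$protein_a, protein_b = split$train$protein_b,
               partition = rep("train", nrow(split$train)), stringsAsFactors = FALSE),
    data.frame(protein_a = split$test$protein_a, protein_b = split$test$protein_b,
               partition = rep("test", nrow(split$test)), stringsAsFactors = FALSE))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a train/test edge split
#'
#' Validates the partition on read: overlapping train/test pairs are an
#' error; an empty test partition is accepted with a warning.
#'
#' @param path Path written by [write_split()].
#' @return A `ppi_split` object.
#' @export
read_split <- function(path) {
  if (!file.exists(path)) stop("split file not found: ", path, call. = FALSE)
  head1 <- readLines(path, n = 1L)
  m <- regmatches(head1, regexec("^#\\s*scheme=(\\S+)\\s+seed=(-?\\d+)", head1))[[1]]
  if (length(m) != 3)
    stop("split file must start with '# scheme=<scheme> seed=<seed>'", call. = FALSE)
  scheme <- m[2]
  if (!scheme %in% c("random", "bfs", "dfs"))
    stop("unknown split scheme tag: ", scheme, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("protein_a", "protein_b", "partition") %in% names(tab)))
    stop("split TSV must have columns protein_a, protein_b, partition", call. = FALSE)
  if (!all(tab$partition %in% c("train", "test")))
    stop("partition values must be 'train' or 'test'", call. = FALSE)
  key <- pair_key(tab$protein_a, tab$protein_b)
  both <- intersect(key[tab$partition == "train"], key[tab$partition == "test"])
  if (length(both) > 0)
    stop("train and test partitions overlap on ", length(both), " edge(s)",
         call. = FALSE)
  take <- function(part) {
    sub <- tab[tab$partition == part, c("protein_a", "protein_b")]
    row.names(sub) <- NULL
    sub
  }
  test <- take("test")
  if (nrow(test) == 0) warning("split has an empty test partition", call. = FALSE)
  new_ppi_split(scheme, as.integer(m[3]), take("train"), test)
}
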
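#' Canonical interaction-type labels
#'
#' The seven interaction types annotated on STRING action edges, in the fixed
#' column order used throughout the package: activation, binding, catalysis,
#' expression, inhibition, ptmod (post-translational modification), reaction.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' ppi_labels()
ppi_labels <- function() {
  c("activation", "binding", "catalysis", "expression",
    "inhibition", "ptmod", "reaction")
}

#' Physicochemical amino-acid class map
#'
#' Partitions the 20 canonical amino acids into the seven conjoint-triad
#' classes of Shen et al. (grouping by dipole moment and side-chain volume):
#' \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\}, \{C\}.
#' Selenocysteine (U), pyrrolysine (O) and every other letter (ambiguity
#' codes, unknown residues) fall into an eighth catch-all class, so every
#' uppercase letter is encodable.
#'
#' @return Named integer vector mapping each of the 26 letters A-Z to a class
#'   index in 1..8.
#' @export
#' @examples
#' cm <- aa_class_map()
#' cm[["C"]]  # 7
#' cm[["U"]]  # 8
aa_class_map <- function() {
  groups <- list(
    c("A", "G", "V"),
    c("I", "L", "F", "P"),
    c("Y", "M", "T", "S"),
    c("H", "N", "Q", "W"),
    c("R", "K"),
    c("D", "E"),
    c("C")
  )
  map <- stats::setNames(rep(8L, 26L), LETTERS)
  for (i in seq_along(groups)) map[groups[[i]]] <- i
  map
}

# The 20 canonical residues, in class order.
canonical_residues <- function() {
  cm <- aa_class_map()
  names(cm)[cm != 8L]
}

# Validate and canonicalize a label vector against the 7-type vocabulary.
# `aliases` admits the long STRING spelling for ptmod.
canonical_label <- function(x) {
  aliases <- c("post-translational modification" = "ptmod",
               "post_translational_modification" = "ptmod",
               "ptmod" = "ptmod")
  x <- tolower(trimws(x))
  x <- ifelse(x %in% names(aliases), aliases[x], x)
  bad <- setdiff(unique(x), ppi_labels())
  if (length(bad) > 0) {
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "),
         "; accepted labels are: ", paste(ppi_labels(), collapse = ", "),
         call. = FALSE)
  }
  unname(x)
}

# labels (character subsets) -> binary matrix (n x 7) in ppi_labels() order
labels_to_matrix <- function(label_sets) {
  lab <- ppi_labels()
  y <- matrix(0L, nrow = length(label_sets), ncol = length(lab),
              dimnames = list(NULL, lab))
  for (i in seq_along(label_sets)) y[i, label_sets[[i]]] <- 1L
  y
}
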
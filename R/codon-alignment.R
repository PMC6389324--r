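#' Codon alignment with ancestral sequences
#'
#' Container for one orthogroup: a gapped in-frame codon alignment of extant
#' species plus ancestral sequences at the named internal nodes of a rooted
#' tree. All sequences share the same length (a multiple of 3); gaps are
#' whole-codon (`---`).
#'
#' @param gene_id Gene / orthogroup identifier.
#' @param sequences Named character vector or list of aligned extant
#'   sequences (A/C/G/T/N/-).
#' @param ancestors Named character vector or list of ancestral sequences;
#'   names must match the tree's internal node labels.
#' @param tree An [ape::phylo] rooted tree with named internal nodes, or
#'   `NULL` when only pairwise use is intended.
#' @return An object of class `codon_alignment` with elements `gene_id`,
#'   `seqs` (all rows, integer-encoded), `tips`, `nodes`, `tree`, `n_sites`.
#' @export
codon_alignment <- function(gene_id, sequences, ancestors = list(), tree = NULL) {
  seqs <- c(as.list(sequences), as.list(ancestors))
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  enc <- lapply(seqs, function(s) if (is.character(s)) dna_to_int(s) else as.integer(s))
  L <- unique(vapply(enc, length, integer(1)))
  if (length(L) != 1L) stop("sequences differ in length")
  if (L %% 3L != 0L) stop("alignment length not a multiple of 3")
  for (nm in names(enc)) {
    g <- matrix(enc[[nm]] == GAP_CODE, nrow = 3L)
    if (any(colSums(g) %in% 1:2))
      stop("partial-codon gap in sequence ", nm, " (frame must be preserved)")
  }
  structure(list(gene_id = gene_id, seqs = enc,
                 tips = names(sequences), nodes = names(ancestors),
                 tree = tree, n_sites = L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment '", x$gene_id, "': ", length(x$tips), " tips + ",
      length(x$nodes), " ancestral rows, ", x$n_sites / 3L, " codons\n", sep = "")
  invisible(x)
}

# Codon index (1..64) vector of one row; NA where the codon contains a gap
# or mask. Used by every counting routine.
codon_indices <- function(aln, name) {
  s <- aln$seqs[[name]]
  if (is.null(s)) stop("unknown sequence: ", name)
  m <- matrix(s, nrow = 3L)
  ok <- m[1, ] %in% 1:4 & m[2, ] %in% 1:4 & m[3, ] %in% 1:4
  out <- rep(NA_integer_, ncol(m))
  out[ok] <- codon_index(m[1, ok], m[2, ok], m[3, ok])
  out
}

# Codons analyzable alignment-wide: no gap/mask in ANY row (extant or
# ancestral) and sense in every row.
analyzable_codons <- function(aln, rows = names(aln$seqs)) {
  ok <- rep(TRUE, aln$n_sites / 3L)
  for (nm in rows) {
    ci <- codon_indices(aln, nm)
    ok <- ok & !is.na(ci) & is_sense_codon_idx(pmax(ci, 1L))
  }
  ok
}

#' Read a codon alignment from FASTA files and a newick tree
#'
#' @param gene_id Identifier for the alignment.
#' @param fasta Path to the FASTA of extant aligned sequences.
#' @param ancestor_fasta Optional FASTA of ancestral sequences keyed by node
#'   name (matching the newick internal-node labels).
#' @param tree_file Optional newick file with named internal nodes.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(gene_id, fasta, ancestor_fasta = NULL, tree_file = NULL) {
  xs <- Biostrings::readBStringSet(fasta)
  seqs <- stats::setNames(as.character(xs), names(xs))
  anc <- list()
  if (!is.null(ancestor_fasta)) {
    xa <- Biostrings::readBStringSet(ancestor_fasta)
    anc <- stats::setNames(as.character(xa), names(xa))
  }
  tree <- if (!is.null(tree_file)) ape::read.tree(tree_file) else NULL
  codon_alignment(gene_id, seqs, anc, tree)
}

#' Write a codon alignment (all rows) to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param file Output path.
#' @param rows Which rows to write (default all: tips then ancestors).
#' @export
write_codon_alignment <- function(aln, file, rows = names(aln$seqs)) {
  ss <- vapply(aln$seqs[rows], int_to_dna, character(1))
  Biostrings::writeXStringSet(Biostrings::BStringSet(ss), filepath = file)
  invisible(file)
}

# Branches of a rooted ape tree as a data.frame of (parent_label,
# child_label); internal labels must be present.
tree_branches <- function(tree) {
  lab <- c(tree$tip.label, tree$node.label)
  data.frame(parent = lab[tree$edge[, 1]], child = lab[tree$edge[, 2]],
             length = if (!is.null(tree$edge.length)) tree$edge.length else NA_real_,
             stringsAsFactors = FALSE)
}

# Parent node label of a tip or internal node.
parent_node <- function(tree, child) {
  br <- tree_branches(tree)
  hit <- br$parent[br$child == child]
  if (length(hit) != 1L) stop("cannot find parent of ", child)
  hit
}
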
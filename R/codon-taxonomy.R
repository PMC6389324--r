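#' Classify a base change as W->S, S->W or GC-conservative
#'
#' The twelve ordered single-base changes partition into three categories of
#' four: `WS` (weak A/T to strong G/C, promoted by GC-biased gene
#' conversion), `SW` (strong to weak, opposed by it), and `CONS`
#' (GC-conservative, A<->T or G<->C, unaffected by it).
#'
#' @param from_base,to_base Single characters in `A`, `C`, `G`, `T`
#'   (vectorised; recycled to common length).
#' @return Character vector with values `"WS"`, `"SW"` or `"CONS"`.
#' @examples
#' classify_change("A", "G")  # "WS"
#' classify_change("G", "C")  # "CONS"
#' @export
classify_change <- function(from_base, to_base) {
  f <- match(toupper(from_base), BASES)
  t <- match(toupper(to_base), BASES)
  if (anyNA(f) || anyNA(t)) stop("invalid nucleotide")
  if (any(f == t)) stop("from_base and to_base must differ")
  fw <- BASE_IS_W[f]; tw <- BASE_IS_W[t]
  ifelse(fw & !tw, "WS", ifelse(!fw & tw, "SW", "CONS"))
}

#' Synonymy of a single-base codon change under the standard genetic code
#'
#' @param codon A sense codon (3 characters, ACGT).
#' @param codon_pos Position of the changing base within the codon, 1-3.
#' @param to_base Replacement base; must differ from `substr(codon, codon_pos,
#'   codon_pos)`.
#' @return `TRUE` if the amino acid is unchanged, `FALSE` otherwise, `NA` if
#'   the mutated codon is a stop codon (flagged; such changes are excluded
#'   from all downstream counts).
#' @export
is_synonymous <- function(codon, codon_pos, to_base) {
  b <- dna_to_int(codon)
  if (length(b) != 3L || any(b < 1L)) stop("codon must be an ungapped 3-mer")
  idx <- codon_index(b[1], b[2], b[3])
  aa <- codon_aa()
  if (aa[idx] == "*") stop("codon is a stop codon")
  tb <- match(toupper(to_base), BASES)
  if (is.na(tb)) stop("invalid nucleotide")
  if (tb == b[codon_pos]) stop("to_base equals the current base")
  nb <- b; nb[codon_pos] <- tb
  to_idx <- codon_index(nb[1], nb[2], nb[3])
  if (aa[to_idx] == "*") return(NA)
  aa[idx] == aa[to_idx]
}

#' GC content at third (or second) codon positions
#'
#' Fraction of G/C among the focal sequence's bases at the given codon
#' position, excluding gaps and masked (`N`) sites.
#'
#' @param aln A [codon_alignment()].
#' @param species Sequence name (tip or internal node).
#' @param pos Codon position, default 3 (GC3); 2 gives GC2.
#' @return Fraction in \[0, 1\]; errors when no usable site remains.
#' @export
gc3 <- function(aln, species, pos = 3L) {
  s <- aln$seqs[[species]]
  if (is.null(s)) stop("unknown sequence: ", species)
  third <- s[seq.int(pos, length(s), by = 3L)]
  third <- third[third %in% 1:4]
  if (length(third) == 0L) stop("no unmasked, ungapped base at codon position ", pos)
  mean(!BASE_IS_W[third])
}

#' Mask alignment columns participating in a CpG dinucleotide
#'
#' A column is masked (set to `N` in every row) when, in any row of the
#' alignment -- extant species and ancestral sequences alike -- the base at
#' that column forms a CpG dinucleotide with its neighbour (C immediately
#' followed by G in alignment coordinates). Masked columns are excluded from
#' all counts, opportunities and SNP sets downstream. The operation is
#' idempotent.
#'
#' @param aln A [codon_alignment()].
#' @return The alignment with masked columns, plus attribute
#'   `n_masked_columns`.
#' @export
mask_cpg_columns <- function(aln) {
  L <- aln$n_sites
  flag <- logical(L)
  for (s in aln$seqs) {
    if (L < 2L) break
    cg <- s[-L] == 2L & s[-1L] == 3L  # C followed by G
    if (any(cg)) {
      w <- which(cg)
      flag[w] <- TRUE
      flag[w + 1L] <- TRUE
    }
  }
  aln$seqs <- lapply(aln$seqs, function(s) { s[flag] <- MASK_CODE; s })
  attr(aln, "n_masked_columns") <- sum(flag)
  aln
}
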
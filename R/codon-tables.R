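# Internal base/codon encodings and precomputed single-base-change tables.
#
# Bases are encoded as integers 1=A, 2=C, 3=G, 4=T; 0 marks a masked site
# ('N') and -1 an alignment gap ('-'). Codons are indexed 1..64 as
# 16*(b1-1) + 4*(b2-1) + b3.

BASES <- c("A", "C", "G", "T")
BASE_IS_W <- c(TRUE, FALSE, FALSE, TRUE)   # weak = A or T
GAP_CODE <- -1L
MASK_CODE <- 0L

#' @importFrom Biostrings GENETIC_CODE
NULL

.codon_cache <- new.env(parent = emptyenv())

dna_to_int <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  out <- match(v, BASES)
  out[v == "-"] <- GAP_CODE
  out[v == "N"] <- MASK_CODE
  if (anyNA(out)) stop("invalid character in sequence: ", paste(unique(v[is.na(out)]), collapse = ","))
  out
}

int_to_dna <- function(x) {
  ch <- character(length(x))
  ok <- x %in% 1:4
  ch[ok] <- BASES[x[ok]]
  ch[x == GAP_CODE] <- "-"
  ch[x == MASK_CODE] <- "N"
  paste(ch, collapse = "")
}

codon_index <- function(b1, b2, b3) 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3

codon_string <- function(idx) {
  i <- idx - 1L
  paste0(BASES[i %/% 16L + 1L], BASES[(i %/% 4L) %% 4L + 1L], BASES[i %% 4L + 1L])
}

# Amino acid (one letter, "*" = stop) for codon indices 1..64, from the
# standard genetic code.
codon_aa <- function() {
  if (!is.null(.codon_cache$aa)) return(.codon_cache$aa)
  gc <- Biostrings::GENETIC_CODE
  codons <- vapply(1:64, codon_string, character(1))
  aa <- unname(gc[codons])
  .codon_cache$aa <- aa
  aa
}

is_sense_codon_idx <- function(idx) codon_aa()[idx] != "*"

# Table of the 9 possible single-base changes for every codon (64 x 9
# matrices; rows for stop codons are present but flagged). Column j encodes
# position p = (j-1) %/% 3 + 1 and the p-th position's j-th alternative base
# in A<C<G<T order.
change_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  aa <- codon_aa()
  TO <- FROMB <- TOB <- POS <- matrix(0L, 64, 9)
  SYN <- TS <- STOPM <- matrix(FALSE, 64, 9)
  CAT <- matrix(0L, 64, 9)  # 1 = WS, 2 = SW, 3 = CONS
  for (idx in 1:64) {
    i <- idx - 1L
    b <- c(i %/% 16L + 1L, (i %/% 4L) %% 4L + 1L, i %% 4L + 1L)
    j <- 0L
    for (p in 1:3) {
      alts <- setdiff(1:4, b[p])
      for (a in alts) {
        j <- j + 1L
        nb <- b; nb[p] <- a
        to_idx <- codon_index(nb[1], nb[2], nb[3])
        TO[idx, j] <- to_idx
        FROMB[idx, j] <- b[p]
        TOB[idx, j] <- a
        POS[idx, j] <- p
        SYN[idx, j] <- aa[idx] == aa[to_idx]
        STOPM[idx, j] <- aa[to_idx] == "*"
        # transitions: A<->G (1,3), C<->T (2,4)
        TS[idx, j] <- (b[p] + a) %in% c(4L, 6L) && abs(b[p] - a) == 2L
        fw <- BASE_IS_W[b[p]]; tw <- BASE_IS_W[a]
        CAT[idx, j] <- if (fw && !tw) 1L else if (!fw && tw) 2L else 3L
      }
    }
  }
  .codon_cache$tab <- list(TO = TO, FROMB = FROMB, TOB = TOB, POS = POS,
                           SYN = SYN, TS = TS, STOP = STOPM, CAT = CAT)
  .codon_cache$tab
}

CATEGORY_LEVELS <- c("WS", "SW", "CONS")
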
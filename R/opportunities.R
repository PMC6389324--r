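#' Per-position mutational-opportunity weights of one codon
#'
#' At each codon position the three alternative bases receive probability
#' weights proportional to `kappa` (the transition) or 1 (each transversion),
#' normalised to sum to one per position, so that every position contributes
#' one "site". Each alternative's weight is attributed to its
#' (category, synonymous/nonsynonymous) cell. Changes creating a stop codon
#' are dropped after normalisation; the dropped weight is reported, not
#' redistributed.
#'
#' @param codon Sense codon (3 characters).
#' @param kappa Transition/transversion ratio, > 0.
#' @return List with `syn` and `nonsyn` (named numeric vectors over
#'   `WS`, `SW`, `CONS`), plus `stop_weight`, the total weight excluded for
#'   stop-producing changes. `syn + nonsyn + stop_weight` sums to 3.
#' @export
site_weights <- function(codon, kappa) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be positive")
  b <- dna_to_int(codon)
  if (length(b) != 3L || any(!b %in% 1:4)) stop("codon must be an ungapped 3-mer")
  idx <- codon_index(b[1], b[2], b[3])
  if (codon_aa()[idx] == "*") stop("stop codon has no mutational opportunities")
  tab <- change_tables()
  w <- ifelse(tab$TS[idx, ], kappa, 1) / (kappa + 2)
  syn <- nonsyn <- stats::setNames(numeric(3), CATEGORY_LEVELS)
  stop_w <- 0
  for (j in 1:9) {
    if (tab$STOP[idx, j]) { stop_w <- stop_w + w[j]; next }
    k <- tab$CAT[idx, j]
    if (tab$SYN[idx, j]) syn[k] <- syn[k] + w[j] else nonsyn[k] <- nonsyn[k] + w[j]
  }
  list(syn = syn, nonsyn = nonsyn, stop_weight = stop_w)
}

# 64 x 7 matrix of per-codon opportunity weights for one kappa:
# columns syn.WS syn.SW syn.CONS nonsyn.WS nonsyn.SW nonsyn.CONS stop.
# Optionally restricted to changes at one codon position (for GC3*).
opportunity_matrix <- function(kappa, pos = NULL) {
  tab <- change_tables()
  aa <- codon_aa()
  M <- matrix(0, 64, 7,
              dimnames = list(NULL, c(paste0("syn.", CATEGORY_LEVELS),
                                      paste0("nonsyn.", CATEGORY_LEVELS), "stop")))
  for (idx in which(aa != "*")) {
    w <- ifelse(tab$TS[idx, ], kappa, 1) / (kappa + 2)
    for (j in 1:9) {
      if (!is.null(pos) && tab$POS[idx, j] != pos) next
      if (tab$STOP[idx, j]) { M[idx, 7] <- M[idx, 7] + w[j]; next }
      col <- tab$CAT[idx, j] + if (tab$SYN[idx, j]) 0L else 3L
      M[idx, col] <- M[idx, col] + w[j]
    }
  }
  M
}

#' Count per-gene mutational opportunities ("numbers of sites")
#'
#' Sums [site_weights()] over all analyzable codons of the focal species'
#' extant sequence, split into synonymous and nonsynonymous opportunities per
#' change category. Codons containing a gap or mask in any alignment row, or
#' a non-sense codon in any row, are excluded.
#'
#' @param aln A [codon_alignment()].
#' @param species Focal sequence name.
#' @param kappa Transition/transversion ratio.
#' @param rows Rows whose gaps/masks define analyzable columns (default: all
#'   rows of the alignment).
#' @return Object of class `opportunity_counts`: list with `gene_id`,
#'   `kappa`, `n_syn` and `n_nonsyn` (named vectors over WS, SW, CONS, ALL),
#'   `stop_weight`, `n_codons`, and `third` (third-position-only opportunity
#'   totals used for GC3*).
#' @export
count_opportunities <- function(aln, species, kappa, rows = names(aln$seqs)) {
  ok <- analyzable_codons(aln, rows)
  ci <- codon_indices(aln, species)
  ci <- ci[ok & !is.na(ci)]
  if (length(ci) == 0L) stop("no analyzable codon for ", species)
  counts <- tabulate(ci, nbins = 64L)
  M <- opportunity_matrix(kappa)
  tot <- as.numeric(counts %*% M)
  names(tot) <- colnames(M)
  M3 <- opportunity_matrix(kappa, pos = 3L)
  tot3 <- as.numeric(counts %*% M3)
  names(tot3) <- colnames(M3)
  n_syn <- c(tot[1:3], ALL = sum(tot[1:3]))
  names(n_syn) <- c(CATEGORY_LEVELS, "ALL")
  n_nonsyn <- c(tot[4:6], ALL = sum(tot[4:6]))
  names(n_nonsyn) <- c(CATEGORY_LEVELS, "ALL")
  structure(list(gene_id = aln$gene_id, species = species, kappa = kappa,
                 n_syn = n_syn, n_nonsyn = n_nonsyn,
                 stop_weight = unname(tot[7]), n_codons = length(ci),
                 third = tot3),
            class = "opportunity_counts")
}

#' Estimate the transition/transversion ratio from 4-fold degenerate sites
#'
#' Pools substitutions (parent vs child differences) at third positions of
#' 4-fold degenerate codon families across alignments, and returns
#' transitions-per-transition-opportunity over
#' transversions-per-transversion-opportunity (each such site offers one
#' transition and two transversions).
#'
#' @param alignments List of [codon_alignment()] objects.
#' @param branches Data frame with columns `parent`, `child` naming the
#'   branch(es) to use; default: every branch of each alignment's tree.
#' @param cap Upper bound returned (with a warning) when no transversion is
#'   observed.
#' @return Positive scalar kappa estimate.
#' @export
estimate_kappa <- function(alignments, branches = NULL, cap = 100) {
  ts <- tv <- 0L
  aa <- codon_aa()
  # 4-fold families: all 4 third bases give the same amino acid
  ff <- vapply(seq.int(1L, 64L, by = 4L), function(s) length(unique(aa[s:(s + 3L)])) == 1L && aa[s] != "*", logical(1))
  fourfold_family <- rep(ff, each = 4L)
  for (aln in alignments) {
    br <- if (is.null(branches)) tree_branches(aln$tree) else branches
    ok <- analyzable_codons(aln)
    for (k in seq_len(nrow(br))) {
      cp <- codon_indices(aln, br$parent[k])
      cc <- codon_indices(aln, br$child[k])
      use <- ok & !is.na(cp) & !is.na(cc) & fourfold_family[pmax(cp, 1L)]
      bp <- (cp[use] - 1L) %% 4L + 1L
      bc <- (cc[use] - 1L) %% 4L + 1L
      same12 <- (cp[use] - 1L) %/% 4L == (cc[use] - 1L) %/% 4L
      d <- which(same12 & bp != bc)
      if (length(d)) {
        is_ts <- abs(bp[d] - bc[d]) == 2L
        ts <- ts + sum(is_ts)
        tv <- tv + sum(!is_ts)
      }
    }
  }
  if (ts + tv == 0L) stop("no substitution observed at 4-fold degenerate sites")
  if (tv == 0L) {
    warning("no transversion observed; kappa capped at ", cap)
    return(cap)
  }
  (ts / 1) / (tv / 2)
}

#' Write opportunity counts for a gene set to TSV
#'
#' @param opps List of `opportunity_counts`.
#' @param file Output path.
#' @export
write_opportunities <- function(opps, file) {
  df <- do.call(rbind, lapply(opps, function(o) {
    data.frame(gene_id = o$gene_id, species = o$species, kappa = o$kappa,
               t(c(stats::setNames(o$n_syn, paste0("syn_", names(o$n_syn))),
                   stats::setNames(o$n_nonsyn, paste0("nonsyn_", names(o$n_nonsyn))))),
               stop_weight = o$stop_weight, check.names = FALSE)
  }))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
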
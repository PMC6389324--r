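# Gene binning by GC3 or recombination rate and bin-level correlation
# statistics (Spearman with exact permutation p-values, BH FDR).

#' Partition genes into bins by a sort key
#'
#' `equal_genes` makes k bins of (almost) equal gene number; `equal_snps`
#' cuts the cumulative SNP counts of the sorted genes at multiples of
#' total/k, so bin SNP totals differ by at most the largest per-gene count.
#' Sorting is by increasing key with ties broken by `gene_id` for
#' determinism.
#'
#' @param gene_id Character vector.
#' @param key Numeric sort key (GC3 or r).
#' @param k Number of bins.
#' @param scheme `"equal_genes"` or `"equal_snps"`.
#' @param weights Per-gene SNP counts (required for `equal_snps`).
#' @return Object of class `gene_binning`: list with `assignment` (named
#'   integer vector gene -> bin, bins ordered by increasing key), `k`,
#'   `scheme`.
#' @export
make_bins <- function(gene_id, key, k, scheme = c("equal_genes", "equal_snps"),
                      weights = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(length(gene_id) == length(key), k <= length(gene_id))
  o <- order(key, gene_id)
  bin <- integer(length(gene_id))
  if (scheme == "equal_genes") {
    sizes <- rep(length(gene_id) %/% k, k)
    extra <- length(gene_id) %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    bin[o] <- rep(seq_len(k), times = sizes)
  } else {
    if (is.null(weights)) stop("equal_snps binning needs per-gene SNP counts")
    w <- weights[o]
    n <- length(w)
    # adaptive greedy cut: each bin targets the remaining mean weight and
    # closes at whichever cut lies closer to it
    bb <- integer(n)
    i <- 1L; remaining <- sum(w)
    for (b in seq_len(k)) {
      target <- remaining / (k - b + 1L)
      tot <- 0
      while (i <= n) {
        if (n - i < k - b) break  # leave one gene for each later bin
        if (b < k && tot > 0 && abs(tot + w[i] - target) >= abs(tot - target)) break
        tot <- tot + w[i]; bb[i] <- b; i <- i + 1L
        if (b == k) next
      }
      remaining <- remaining - tot
    }
    if (i <= n) bb[i:n] <- k
    bin[o] <- bb
  }
  structure(list(assignment = stats::setNames(bin, gene_id), k = k, scheme = scheme),
            class = "gene_binning")
}

# Exact null distribution of Spearman's rho for n distinct ranks, by full
# permutation enumeration (cached per n; used for n <= 10 where 10! = 3.6M).
.spearman_null <- function(n) {
  key <- paste0("sp", n)
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  perms <- matrix(1L, 1, 1)
  for (m in 2:n) {
    nr <- nrow(perms)
    out <- matrix(0L, nr * m, m)
    for (pos in seq_len(m)) {
      rows <- (pos - 1L) * nr + seq_len(nr)
      out[rows, pos] <- m
      out[rows, -pos] <- perms
    }
    perms <- out
  }
  base <- seq_len(n)
  S <- rowSums((perms - matrix(base, nrow(perms), n, byrow = TRUE))^2)
  rho <- 1 - 6 * S / (n * (n^2 - 1))
  .codon_cache[[key]] <- rho
  rho
}

#' Spearman correlation over bins with exact permutation p-value
#'
#' Rank correlation of bin-level values (e.g. mean GC3 per bin against a
#' per-bin statistic). For 10 or fewer bins the two-sided p-value is exact,
#' from full enumeration of the `n!` rank permutations; beyond that it
#' falls back to [stats::cor.test()]'s AS 89 approximation.
#'
#' @param x,y Numeric vectors (one value per bin).
#' @return List with `rho` and `p` (`rho = NA`, flagged with a warning, when
#'   either vector is constant).
#' @export
spearman_bins <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 bins with defined values")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant values: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (n <= 10L && !anyDuplicated(x) && !anyDuplicated(y)) {
    null <- .spearman_null(n)
    p <- mean(abs(null) >= abs(rho) - 1e-12)
  } else {
    p <- suppressWarnings(stats::cor.test(x, y, method = "spearman")$p.value)
  }
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control applied across one family of tests
#' (all species x statistics of one table).
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (monotone, bounded by 1).
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Per-bin statistics and Spearman table for a gene set
#'
#' Computes, per bin of a [make_bins()] partition, pooled dN, dS and dN/dS
#' (ratio of sums) for each change category, then the Spearman correlation
#' of each statistic against the per-bin mean key, with BH-adjusted
#' p-values across the table.
#'
#' @param binning A `gene_binning`.
#' @param key Named per-gene key values (same genes).
#' @param subs,opps Named lists of `substitution_set` / `opportunity_counts`
#'   keyed by gene.
#' @param categories Categories to tabulate.
#' @return List with `per_bin` (long data frame: bin, mean_key, category,
#'   dN, dS, omega) and `correlations` (statistic, category, rho, p, p_fdr).
#' @export
bin_divergence_table <- function(binning, key, subs, opps,
                                 categories = c("ALL", CATEGORY_LEVELS)) {
  genes <- names(binning$assignment)
  per_bin <- list()
  for (b in seq_len(binning$k)) {
    gb <- genes[binning$assignment == b]
    for (cat in categories) {
      re <- rate_estimate(subs[gb], opps[gb], category = cat, n_boot = 0)
      per_bin[[length(per_bin) + 1L]] <-
        data.frame(bin = b, mean_key = mean(key[gb]), category = cat,
                   dN = re$dN, dS = re$dS, omega = re$omega,
                   stringsAsFactors = FALSE)
    }
  }
  per_bin <- do.call(rbind, per_bin)
  rows <- list()
  for (cat in categories) {
    sub <- per_bin[per_bin$category == cat, ]
    for (stat in c("dN", "dS", "omega")) {
      ct <- spearman_bins(sub$mean_key, sub[[stat]])
      rows[[length(rows) + 1L]] <-
        data.frame(statistic = stat, category = cat, rho = ct$rho, p = ct$p,
                   stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, rows)
  correlations$p_fdr <- fdr_adjust(correlations$p)
  list(per_bin = per_bin, correlations = correlations)
}
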
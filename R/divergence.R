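#' Count substitutions on a branch by parent-child differencing
#'
#' Compares the supplied ancestral (parent) sequence with the child sequence
#' codon by codon over analyzable columns. Codons differing at a single
#' position yield one record; codons differing at 2-3 positions are
#' decomposed by averaging the synonymous/nonsynonymous and category
#' attribution over all minimal mutational paths that avoid stop codons
#' (records then carry fractional `weight`).
#'
#' @param aln A [codon_alignment()].
#' @param parent,child Row names of the branch's parent and child sequences.
#' @param exclude_codons Optional logical vector (one per codon) of columns
#'   to skip, e.g. codons polymorphic in the focal species.
#' @return Object of class `substitution_set`: list with `gene_id`, `branch`
#'   and `records`, a data frame with columns `codon` (1-based codon index),
#'   `pos` (1-3), `column` (1-based alignment column), `from_base`,
#'   `to_base`, `syn`, `category`, `weight`.
#' @export
count_substitutions <- function(aln, parent, child, exclude_codons = NULL) {
  ok <- analyzable_codons(aln)
  if (!is.null(exclude_codons)) ok <- ok & !exclude_codons
  cp <- codon_indices(aln, parent)
  cc <- codon_indices(aln, child)
  use <- which(ok & !is.na(cp) & !is.na(cc) & cp != cc)
  recs <- vector("list", length(use))
  for (i in seq_along(use)) {
    k <- use[i]
    recs[[i]] <- decompose_codon_change(cp[k], cc[k], k)
  }
  records <- if (length(recs)) do.call(rbind, recs) else empty_records()
  structure(list(gene_id = aln$gene_id, branch = c(parent = parent, child = child),
                 records = records),
            class = "substitution_set")
}

empty_records <- function() {
  data.frame(codon = integer(), pos = integer(), column = integer(),
              from_base = character(), to_base = character(),
              syn = logical(), category = character(), weight = numeric(),
              stringsAsFactors = FALSE)
}

codon_bases <- function(idx) {
  i <- idx - 1L
  c(i %/% 16L + 1L, (i %/% 4L) %% 4L + 1L, i %% 4L + 1L)
}

# All minimal mutational paths between two codons, skipping paths through
# stop codons; attribution averaged over surviving paths.
decompose_codon_change <- function(from_idx, to_idx, codon_k) {
  aa <- codon_aa()
  bf <- codon_bases(from_idx); bt <- codon_bases(to_idx)
  dif <- which(bf != bt)
  orders <- permutations_of(dif)
  acc <- list()
  n_ok <- 0L
  for (ord in orders) {
    cur <- bf
    steps <- list()
    valid <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- bt[p]
      from_i <- codon_index(cur[1], cur[2], cur[3])
      to_i <- codon_index(nxt[1], nxt[2], nxt[3])
      if (aa[to_i] == "*") { valid <- FALSE; break }  # never pass through stops
      steps[[length(steps) + 1L]] <-
        list(pos = p, from = cur[p], to = bt[p],
             syn = aa[from_i] == aa[to_i],
             cat = classify_change(BASES[cur[p]], BASES[bt[p]]))
      cur <- nxt
    }
    if (valid) { n_ok <- n_ok + 1L; acc[[n_ok]] <- steps }
  }
  if (n_ok == 0L) return(empty_records())  # all paths blocked by stops; codon skipped
  out <- list()
  for (steps in acc) for (st in steps) {
    key <- paste(st$pos, st$from, st$to, st$syn, st$cat)
    if (is.null(out[[key]])) {
      out[[key]] <- data.frame(codon = codon_k, pos = st$pos,
                               column = (codon_k - 1L) * 3L + st$pos,
                               from_base = BASES[st$from], to_base = BASES[st$to],
                               syn = st$syn, category = st$cat,
                               weight = 1 / n_ok, stringsAsFactors = FALSE)
    } else out[[key]]$weight <- out[[key]]$weight + 1 / n_ok
  }
  do.call(rbind, unname(out))
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Per-gene substitution totals: named vector over syn/nonsyn x category/ALL.
substitution_totals <- function(subs) {
  r <- subs$records
  tot <- numeric(8)
  names(tot) <- c(paste0("syn_", c(CATEGORY_LEVELS, "ALL")),
                  paste0("nonsyn_", c(CATEGORY_LEVELS, "ALL")))
  if (nrow(r)) {
    for (cat in CATEGORY_LEVELS) {
      tot[paste0("syn_", cat)] <- sum(r$weight[r$syn & r$category == cat])
      tot[paste0("nonsyn_", cat)] <- sum(r$weight[!r$syn & r$category == cat])
    }
    tot["syn_ALL"] <- sum(r$weight[r$syn])
    tot["nonsyn_ALL"] <- sum(r$weight[!r$syn])
  }
  tot
}

#' Pooled dN, dS and dN/dS for a gene set and category
#'
#' Ratio of sums, never mean of ratios: substitutions and opportunity
#' ("number of sites") totals are summed across genes before dividing.
#' Confidence intervals are percentile bootstrap over genes.
#'
#' @param subs List of `substitution_set` (one per gene, same branch).
#' @param opps List of `opportunity_counts` for the same genes and species.
#' @param category `"WS"`, `"SW"`, `"CONS"` or `"ALL"`.
#' @param n_boot Bootstrap replicates for the 95% CI (default 1000); 0
#'   disables the CI.
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `rate_estimate`: list with `dN`, `dS`, `omega`
#'   (NA-flagged when `dS` is 0), per-quantity CIs and the category.
#' @export
rate_estimate <- function(subs, opps, category = "ALL", n_boot = 1000, seed = 1L) {
  stopifnot(length(subs) == length(opps))
  D <- t(vapply(subs, substitution_totals, numeric(8)))
  Ls <- vapply(opps, function(o) o$n_syn[[category]], numeric(1))
  Ln <- vapply(opps, function(o) o$n_nonsyn[[category]], numeric(1))
  if (sum(Ls) <= 0 || sum(Ln) <= 0) stop("zero opportunity total for category ", category)
  ds_num <- D[, paste0("syn_", category)]
  dn_num <- D[, paste0("nonsyn_", category)]
  point <- function(idx) {
    dS <- sum(ds_num[idx]) / sum(Ls[idx])
    dN <- sum(dn_num[idx]) / sum(Ln[idx])
    c(dN = dN, dS = dS, omega = if (dS > 0) dN / dS else NA_real_)
  }
  est <- point(seq_along(subs))
  ci <- NULL
  if (n_boot > 0 && length(subs) >= 2) {
    boot <- bootstrap_ci(length(subs), function(idx) point(idx), n_boot, seed = seed)
    ci <- boot
  }
  structure(list(category = category, dN = est[["dN"]], dS = est[["dS"]],
                 omega = est[["omega"]], ci = ci,
                 D_syn = sum(ds_num), D_nonsyn = sum(dn_num),
                 L_syn = sum(Ls), L_nonsyn = sum(Ln)),
            class = "rate_estimate")
}

#' Percentile bootstrap over genes
#'
#' Resamples gene indices with replacement and returns the 2.5% and 97.5%
#' percentile bounds of the statistic. Fully deterministic for a given seed.
#'
#' @param n_genes Number of genes.
#' @param statistic Function of an index vector returning a numeric (scalar
#'   or named vector).
#' @param n_reps Number of bootstrap replicates (the divergence analyses use
#'   1000, diversity analyses 100).
#' @param seed RNG seed.
#' @param probs Quantile bounds, default `c(0.025, 0.975)`.
#' @return Matrix with one row per statistic component, columns `low`, `high`.
#' @export
bootstrap_ci <- function(n_genes, statistic, n_reps = 1000, seed = 1L,
                         probs = c(0.025, 0.975)) {
  if (n_genes < 2) stop("need >= 2 genes to bootstrap")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reps <- vapply(seq_len(n_reps), function(r) {
    statistic(sample.int(n_genes, n_genes, replace = TRUE))
  }, statistic(seq_len(n_genes)))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  out <- t(apply(reps, 1, stats::quantile, probs = probs, na.rm = TRUE, names = FALSE))
  colnames(out) <- c("low", "high")
  rownames(out) <- rownames(reps)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Equilibrium GC content at third codon positions (GC3*)
#'
#' GC3* = r_WS / (r_WS + r_SW), where r_WS is the third-position W->S
#' substitution count per third-position W->S opportunity and r_SW the
#' analogous S->W rate: the stationary GC under the current substitution
#' process.
#'
#' @param subs,opps Lists of `substitution_set` / `opportunity_counts` for
#'   one gene set.
#' @return Fraction in \[0, 1\]; `NA` (flagged with a warning) when both
#'   rates are zero.
#' @export
gc3_star <- function(subs, opps) {
  ws_sub <- sum(vapply(subs, function(s) {
    r <- s$records; sum(r$weight[r$pos == 3L & r$category == "WS"])
  }, numeric(1)))
  sw_sub <- sum(vapply(subs, function(s) {
    r <- s$records; sum(r$weight[r$pos == 3L & r$category == "SW"])
  }, numeric(1)))
  ws_opp <- sum(vapply(opps, function(o) o$third[["syn.WS"]] + o$third[["nonsyn.WS"]], numeric(1)))
  sw_opp <- sum(vapply(opps, function(o) o$third[["syn.SW"]] + o$third[["nonsyn.SW"]], numeric(1)))
  if (ws_opp <= 0 || sw_opp <= 0) stop("no third-position WS/SW opportunity")
  r_ws <- ws_sub / ws_opp
  r_sw <- sw_sub / sw_opp
  if (r_ws + r_sw == 0) { warning("both WS and SW rates are zero; GC3* undefined"); return(NA_real_) }
  r_ws / (r_ws + r_sw)
}
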
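#' Orient and classify SNPs with ancestral sequences
#'
#' The ancestral state of a SNP is the state of the focal species' immediate
#' parent node at the SNP column; the derived allele is the other observed
#' allele. The change is classified as synonymous/nonsynonymous and
#' W->S / S->W / GC-conservative on the ancestral-to-derived direction using
#' the ancestral codon context. SNPs at masked or gapped columns, tri-allelic
#' sites, stop-involving changes and SNPs whose ancestral state matches
#' neither allele ("unorientable") are dropped and counted.
#'
#' @param snps Data frame with columns `gene_id`, `column` (1-based
#'   alignment column), `allele1`, `allele2` (single bases), `count1`,
#'   `count2` (chromosome counts, summing to the sample size n).
#' @param alignments Named list of [codon_alignment()] keyed by `gene_id`.
#' @param species Focal species (tip name).
#' @return Object of class `snp_records`: list with `records` (data frame
#'   with `gene_id`, `column`, `codon`, `ancestral`, `derived`,
#'   `derived_count`, `n`, `syn`, `category`) and `dropped`, a named count of
#'   discarded SNPs by reason.
#' @export
orient_and_classify <- function(snps, alignments, species) {
  need <- c("gene_id", "column", "allele1", "allele2", "count1", "count2")
  if (!all(need %in% names(snps))) stop("snps must have columns ", paste(need, collapse = ", "))
  dropped <- c(unorientable = 0L, masked_or_gap = 0L, triallelic = 0L,
               stop_or_invalid = 0L, monomorphic = 0L)
  out <- vector("list", nrow(snps))
  aa <- codon_aa()
  parents <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(snps))) {
    g <- as.character(snps$gene_id[i])
    aln <- alignments[[g]]
    if (is.null(aln)) stop("no alignment for gene ", g)
    if (is.null(parents[[g]])) parents[[g]] <- parent_node(aln$tree, species)
    a1 <- toupper(snps$allele1[i]); a2 <- toupper(snps$allele2[i])
    if (nchar(a1) != 1L || nchar(a2) != 1L || !a1 %in% BASES || !a2 %in% BASES) {
      dropped["triallelic"] <- dropped["triallelic"] + 1L; next
    }
    if (a1 == a2 || snps$count1[i] == 0L || snps$count2[i] == 0L) {
      dropped["monomorphic"] <- dropped["monomorphic"] + 1L; next
    }
    col <- as.integer(snps$column[i])
    anc_seq <- aln$seqs[[parents[[g]]]]
    ab <- anc_seq[col]
    if (!ab %in% 1:4) { dropped["masked_or_gap"] <- dropped["masked_or_gap"] + 1L; next }
    # focal sequence must also be unmasked/ungapped there
    if (!aln$seqs[[species]][col] %in% 1:4) {
      dropped["masked_or_gap"] <- dropped["masked_or_gap"] + 1L; next
    }
    anc <- BASES[ab]
    if (anc != a1 && anc != a2) { dropped["unorientable"] <- dropped["unorientable"] + 1L; next }
    derived <- if (anc == a1) a2 else a1
    dcount <- if (anc == a1) snps$count2[i] else snps$count1[i]
    n <- snps$count1[i] + snps$count2[i]
    codon_k <- (col - 1L) %/% 3L + 1L
    pos <- (col - 1L) %% 3L + 1L
    cb <- anc_seq[(codon_k - 1L) * 3L + 1:3]
    if (any(!cb %in% 1:4)) { dropped["masked_or_gap"] <- dropped["masked_or_gap"] + 1L; next }
    cidx <- codon_index(cb[1], cb[2], cb[3])
    if (aa[cidx] == "*") { dropped["stop_or_invalid"] <- dropped["stop_or_invalid"] + 1L; next }
    syn <- is_synonymous(codon_string(cidx), pos, derived)
    if (is.na(syn)) { dropped["stop_or_invalid"] <- dropped["stop_or_invalid"] + 1L; next }
    out[[i]] <- data.frame(gene_id = g, column = col, codon = codon_k,
                           ancestral = anc, derived = derived,
                           derived_count = as.integer(dcount), n = as.integer(n),
                           syn = syn, category = classify_change(anc, derived),
                           stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(records))
    records <- data.frame(gene_id = character(), column = integer(), codon = integer(),
                          ancestral = character(), derived = character(),
                          derived_count = integer(), n = integer(), syn = logical(),
                          category = character(), stringsAsFactors = FALSE)
  structure(list(records = records, species = species, dropped = dropped),
            class = "snp_records")
}

subset_records <- function(records, category = "ALL") {
  if (category == "ALL") records else records[records$category == category, , drop = FALSE]
}

#' Build an unfolded site frequency spectrum pair
#'
#' Tabulates oriented SNPs by derived-allele count into synonymous and
#' nonsynonymous unfolded spectra for one category (or ALL), and attaches the
#' matching opportunity totals and divergence counts for the same gene set,
#' as needed by the DFE estimator.
#'
#' @param snp_records A `snp_records` object (or its `records` data frame).
#' @param opps List of `opportunity_counts` for the same genes.
#' @param subs Optional list of `substitution_set` for the same genes and
#'   the focal terminal branch (fills the divergence counts `D_syn`,
#'   `D_nonsyn`).
#' @param category `"WS"`, `"SW"`, `"CONS"` or `"ALL"`.
#' @param n Sample size (number of chromosomes); taken from the records when
#'   omitted, which errors on mixed n (use [project_sfs()] first).
#' @return Object of class `sfs_pair`: list with `category`, `n`, `syn_sfs`,
#'   `nonsyn_sfs` (length n-1), `L_syn`, `L_nonsyn`, `D_syn`, `D_nonsyn`.
#' @export
build_sfs <- function(snp_records, opps, subs = NULL, category = "ALL", n = NULL) {
  rec <- if (inherits(snp_records, "snp_records")) snp_records$records else snp_records
  rec <- subset_records(rec, category)
  if (is.null(n)) {
    nu <- unique(rec$n)
    if (length(nu) > 1L) stop("mixed sample sizes; project the SFS to a common n first")
    if (length(nu) == 0L) stop("no SNP record; pass n explicitly")
    n <- nu
  }
  if (nrow(rec) && any(rec$n != n)) stop("records with n != ", n)
  tab_of <- function(sub) tabulate(sub$derived_count, nbins = n - 1L)
  syn_sfs <- tab_of(rec[rec$syn, , drop = FALSE])
  nonsyn_sfs <- tab_of(rec[!rec$syn, , drop = FALSE])
  L_syn <- sum(vapply(opps, function(o) o$n_syn[[category]], numeric(1)))
  L_nonsyn <- sum(vapply(opps, function(o) o$n_nonsyn[[category]], numeric(1)))
  D_syn <- D_nonsyn <- NA_real_
  if (!is.null(subs)) {
    D <- rowSums(vapply(subs, substitution_totals, numeric(8)))
    D_syn <- D[[paste0("syn_", category)]]
    D_nonsyn <- D[[paste0("nonsyn_", category)]]
  }
  structure(list(category = category, n = as.integer(n),
                 syn_sfs = syn_sfs, nonsyn_sfs = nonsyn_sfs,
                 L_syn = L_syn, L_nonsyn = L_nonsyn,
                 D_syn = D_syn, D_nonsyn = D_nonsyn),
            class = "sfs_pair")
}

#' Nucleotide diversity per site from oriented SNPs
#'
#' Unbiased pairwise diversity: each SNP with derived count i in n
#' chromosomes contributes 2 i (n - i) / (n (n - 1)), divided by the
#' matching opportunity total.
#'
#' @param snp_records `snp_records` object or records data frame.
#' @param opps List of `opportunity_counts` for the same genes.
#' @param category Change category or `"ALL"`.
#' @return List with `pi_n`, `pi_s`, `ratio` (`NA`-flagged when `pi_s` = 0).
#' @export
pi_diversity <- function(snp_records, opps, category = "ALL") {
  rec <- if (inherits(snp_records, "snp_records")) snp_records$records else snp_records
  rec <- subset_records(rec, category)
  L_syn <- sum(vapply(opps, function(o) o$n_syn[[category]], numeric(1)))
  L_nonsyn <- sum(vapply(opps, function(o) o$n_nonsyn[[category]], numeric(1)))
  if (L_syn <= 0 || L_nonsyn <= 0) stop("zero opportunity total")
  contrib <- function(sub) {
    if (!nrow(sub)) return(0)
    sum(2 * sub$derived_count * (sub$n - sub$derived_count) / (sub$n * (sub$n - 1)))
  }
  pi_s <- contrib(rec[rec$syn, , drop = FALSE]) / L_syn
  pi_n <- contrib(rec[!rec$syn, , drop = FALSE]) / L_nonsyn
  list(pi_n = pi_n, pi_s = pi_s,
       ratio = if (pi_s > 0) pi_n / pi_s else NA_real_)
}

#' Mean derived allele frequency
#'
#' @param snp_records `snp_records` object or records data frame.
#' @param category Change category or `"ALL"`.
#' @param syn `TRUE` for synonymous SNPs only, `FALSE` for nonsynonymous,
#'   `NULL` (default) for all.
#' @return Mean of derived_count / n over the selected records.
#' @export
mean_derived_freq <- function(snp_records, category = "ALL", syn = NULL) {
  rec <- if (inherits(snp_records, "snp_records")) snp_records$records else snp_records
  rec <- subset_records(rec, category)
  if (!is.null(syn)) rec <- rec[rec$syn == syn, , drop = FALSE]
  if (!nrow(rec)) stop("no SNP record in selection")
  mean(rec$derived_count / rec$n)
}

#' Hypergeometric down-projection of an SFS
#'
#' Projects an unfolded spectrum observed in n chromosomes down to a target
#' sample size by hypergeometric expectation (the standard treatment of
#' missing genotypes). Classes projected to frequency 0 or n_target are
#' excluded; entries are expected (real-valued) counts.
#'
#' @param sfs Numeric vector of length n - 1 (counts for derived counts
#'   1..n-1).
#' @param n Original sample size.
#' @param n_target Target sample size, `<= n`.
#' @return Numeric vector of length `n_target - 1`.
#' @export
project_sfs <- function(sfs, n, n_target) {
  if (length(sfs) != n - 1L) stop("sfs must have length n - 1")
  if (n_target > n) stop("n_target must be <= n")
  if (n_target == n) return(sfs)
  out <- numeric(n_target - 1L)
  for (i in seq_len(n - 1L)) {
    if (sfs[i] == 0) next
    for (j in seq_len(n_target - 1L)) {
      out[j] <- out[j] + sfs[i] * stats::dhyper(j, i, n - i, n_target)
    }
  }
  out
}

#' Write / read an SFS pair in a Grapes/dadi-like text layout
#'
#' Plain text: a comment header, then one line `n <L_syn> <L_nonsyn> <D_syn>
#' <D_nonsyn> <category>`, then the synonymous and nonsynonymous spectra as
#' whitespace-separated rows of n-1 counts.
#'
#' @param sfs An `sfs_pair`.
#' @param file Path.
#' @return `read_sfs` returns an `sfs_pair`.
#' @export
write_sfs <- function(sfs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# unfolded SFS pair (syn row, nonsyn row)",
               paste(sfs$n, sfs$L_syn, sfs$L_nonsyn, sfs$D_syn, sfs$D_nonsyn, sfs$category),
               paste(sfs$syn_sfs, collapse = " "),
               paste(sfs$nonsyn_sfs, collapse = " ")), con)
  invisible(file)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(file) {
  ln <- readLines(file)
  ln <- ln[!startsWith(ln, "#")]
  hd <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  structure(list(category = hd[6], n = as.integer(hd[1]),
                 syn_sfs = as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]]),
                 nonsyn_sfs = as.numeric(strsplit(trimws(ln[3]), "\\s+")[[1]]),
                 L_syn = as.numeric(hd[2]), L_nonsyn = as.numeric(hd[3]),
                 D_syn = as.numeric(hd[4]), D_nonsyn = as.numeric(hd[5])),
            class = "sfs_pair")
}
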
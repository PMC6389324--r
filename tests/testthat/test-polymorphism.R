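make_pair_list <- function(parent, child) {
  aln <- pair_alignment(parent, child)
  stats::setNames(list(aln), aln$gene_id)
}

test_that("SNPs are oriented by the parent-node state and classified", {
  alns <- make_pair_list("AAAGGG", "AAAGGG")
  snps <- data.frame(gene_id = "g1", column = 3L, allele1 = "A", allele2 = "G",
                     count1 = 7L, count2 = 3L)
  rec <- orient_and_classify(snps, alns, "sp1")
  expect_equal(nrow(rec$records), 1L)
  r <- rec$records
  expect_equal(r$ancestral, "A")
  expect_equal(r$derived, "G")
  expect_equal(r$derived_count, 3L)
  expect_equal(r$category, "WS")
  expect_true(r$syn)  # AAA -> AAG, Lys
})

test_that("unorientable, masked and stop-involving SNPs are dropped and counted", {
  alns <- make_pair_list("CCCTGG", "CCCTGG")
  snps <- data.frame(gene_id = "g1",
                     column = c(1L, 6L),
                     allele1 = c("A", "G"), allele2 = c("T", "A"),
                     count1 = c(5L, 5L), count2 = c(5L, 5L))
  # SNP 1: ancestor C matches neither allele; SNP 2: TGG -> TGA creates a stop
  rec <- orient_and_classify(snps, alns, "sp1")
  expect_equal(nrow(rec$records), 0L)
  expect_equal(rec$dropped[["unorientable"]], 1L)
  expect_equal(rec$dropped[["stop_or_invalid"]], 1L)
  # SNP in a CpG-masked column is dropped when masking is applied
  alns2 <- lapply(make_pair_list("ACGGGG", "ACGGGG"), mask_cpg_columns)
  snps2 <- data.frame(gene_id = "g1", column = 2L, allele1 = "C", allele2 = "T",
                      count1 = 8L, count2 = 2L)
  rec2 <- orient_and_classify(snps2, alns2, "sp1")
  expect_equal(rec2$dropped[["masked_or_gap"]], 1L)
})

test_that("build_sfs tabulates by derived count and conserves totals", {
  alns <- make_pair_list(strrep("AAA", 10), strrep("AAA", 10))
  snps <- data.frame(gene_id = "g1", column = 3 * (1:5), allele1 = "A",
                     allele2 = "G", count1 = 9L, count2 = 1L)
  rec <- orient_and_classify(snps, alns, "sp1")
  opps <- list(count_opportunities(alns[[1]], "sp1", 2))
  sfs <- build_sfs(rec, opps, category = "ALL", n = 10)
  expect_equal(sfs$syn_sfs, c(5, rep(0, 8)))
  expect_equal(sum(sfs$syn_sfs) + sum(sfs$nonsyn_sfs), nrow(rec$records))
  expect_error(build_sfs(rec, opps, category = "ALL", n = 8), "n != 8")
})

test_that("pi matches its closed form", {
  # one SNP at i = 1, n = 2 over L = 1 site: pi = 2*1*1/(2*1) / 1 = 1
  rec <- data.frame(gene_id = "g", column = 1L, codon = 1L, ancestral = "A",
                    derived = "G", derived_count = 1L, n = 2L, syn = TRUE,
                    category = "WS")
  opp <- structure(list(gene_id = "g", species = "s", kappa = 1,
                        n_syn = c(WS = 1, SW = 0, CONS = 0, ALL = 1),
                        n_nonsyn = c(WS = 1, SW = 0, CONS = 0, ALL = 1),
                        stop_weight = 0, third = numeric(7)),
                   class = "opportunity_counts")
  pis <- pi_diversity(rec, list(opp))
  expect_equal(pis$pi_s, 1)
  expect_equal(pis$pi_n, 0)
  expect_true(is.na(pi_diversity(rec[0, ], list(opp))$ratio))  # pi_s = 0 flagged
})

test_that("mean derived frequency behaves as stated", {
  rec <- data.frame(gene_id = "g", column = 1L, codon = 1L, ancestral = "A",
                    derived = "G", derived_count = 3L, n = 10L, syn = TRUE,
                    category = "WS")
  expect_equal(mean_derived_freq(rec), 0.3)
  sym <- rec[rep(1, 4), ]; sym$derived_count <- c(2L, 8L, 3L, 7L)
  expect_equal(mean_derived_freq(sym), 0.5)
  expect_error(mean_derived_freq(rec[0, ]), "no SNP")
})

test_that("hypergeometric projection is exact against enumeration", {
  expect_equal(project_sfs(c(3, 1, 4), 4, 4), c(3, 1, 4))
  # sfs [0,2,0] at n=4 projected to n=2: for i=2, P(j=1) = choose(2,1)choose(2,1)/choose(4,2)
  got <- project_sfs(c(0, 2, 0), 4, 2)
  expect_equal(got, 2 * choose(2, 1) * choose(2, 1) / choose(4, 2))
  # neutral 1/i shape is preserved in expectation
  n <- 12; m <- 6
  neutral <- 1 / seq_len(n - 1)
  proj <- project_sfs(neutral, n, m)
  expect_equal(proj, 1 / seq_len(m - 1), tolerance = 1e-12)
  expect_error(project_sfs(c(1, 1, 1), 4, 6), "<= n")
})

test_that("orientation round-trips perfectly on synthetic truth", {
  sim <- simulate_alignments(tiny_config(seed = 6, B_range = c(1, 1)))
  sn <- simulate_snps(sim)
  rec <- orient_and_classify(sn$snps, sim$alignments, "sp1")
  expect_equal(sum(rec$dropped), 0L)
  m <- merge(rec$records, sn$truth, by = c("gene_id", "column"))
  expect_equal(nrow(m), nrow(rec$records))
  expect_true(all(m$derived.x == m$derived.y))
  expect_true(all(m$derived_count.x == m$derived_count.y))
  expect_true(all(m$category.x == m$category.y))
  expect_true(all(m$syn.x == m$syn.y))
})

test_that("CpG masking never increases total synonymous diversity", {
  # Masking can only remove SNPs, so the unnormalised pairwise diversity is
  # nonincreasing on any input. (The per-site pi_s need not be: without CpG
  # hypermutability the masked columns are an unbiased-or-better subset, so
  # numerator and denominator shrink together; see the methods vignette.)
  sim <- simulate_alignments(tiny_config(seed = 8))
  sn <- simulate_snps(sim)
  opps <- lapply(sim$alignments, count_opportunities, species = "sp1", kappa = 2)
  rec <- orient_and_classify(sn$snps, sim$alignments, "sp1")
  masked <- lapply(sim$alignments, mask_cpg_columns)
  opps_m <- lapply(masked, count_opportunities, species = "sp1", kappa = 2)
  rec_m <- orient_and_classify(sn$snps, masked, "sp1")
  pi_num <- function(r, o, L) pi_diversity(r, o)$pi_s * L
  L_raw <- sum(vapply(opps, function(o) o$n_syn[["ALL"]], numeric(1)))
  L_m <- sum(vapply(opps_m, function(o) o$n_syn[["ALL"]], numeric(1)))
  expect_lte(pi_num(rec_m, opps_m, L_m), pi_num(rec, opps, L_raw))
  expect_lte(L_m, L_raw)
  expect_lte(nrow(rec_m$records), nrow(rec$records))
})

test_that("SFS files round-trip", {
  sfs <- structure(list(category = "WS", n = 6L, syn_sfs = c(4, 2, 1, 0, 1),
                        nonsyn_sfs = c(2, 0, 0, 1, 0), L_syn = 100.5,
                        L_nonsyn = 300.25, D_syn = 12, D_nonsyn = 3.5),
                   class = "sfs_pair")
  f <- withr::local_tempfile(fileext = ".txt")
  write_sfs(sfs, f)
  back <- read_sfs(f)
  expect_equal(back, sfs)
})
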
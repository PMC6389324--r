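test_that("simulation is byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 21, B_range = c(0, 2))
  s1 <- simulate_alignments(cfg)
  s2 <- simulate_alignments(cfg)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$truth$events, s2$truth$events)
  expect_identical(simulate_snps(s1)$snps, simulate_snps(s2)$snps)
})

test_that("zero-length branches leave the child identical to the parent", {
  cfg <- tiny_config(seed = 22, tree = "((sp1:0.0,sp2:0.1)n1:0.05,sp3:0.1)root;")
  sim <- simulate_alignments(cfg)
  for (aln in sim$alignments[1:5])
    expect_identical(aln$seqs$sp1, aln$seqs$n1)
})

test_that("recorded events match direct parent-child differencing", {
  # short branches: almost no codon is hit twice, so net differences equal events
  cfg <- sim_config(seed = 23, n_genes = 20, codons_per_gene = 100,
                    tree = "((sp1:0.01,sp2:0.01)n1:0.01,sp3:0.02)root;")
  sim <- simulate_alignments(cfg)
  ev <- sim$truth$events
  ev_sp1 <- ev[ev$branch == "sp1", ]
  multi <- unique(ev_sp1[duplicated(ev_sp1[c("gene_id", "codon")]), c("gene_id", "codon")])
  subs <- lapply(sim$alignments, count_substitutions, parent = "n1", child = "sp1")
  got <- do.call(rbind, lapply(subs, function(s) s$records))
  got$gene_id <- rep(names(subs), vapply(subs, function(s) nrow(s$records), integer(1)))
  # restrict to codons hit exactly once
  key <- function(d) paste(d$gene_id, d$codon)
  got1 <- got[!key(got) %in% key(multi), ]
  ev1 <- ev_sp1[!key(ev_sp1) %in% key(multi), ]
  ev1 <- ev1[order(ev1$gene_id, ev1$column), ]
  got1 <- got1[order(got1$gene_id, got1$column), ]
  expect_equal(nrow(got1), nrow(ev1))
  expect_equal(got1$from_base, ev1$from_base)
  expect_equal(got1$to_base, ev1$to_base)
  expect_equal(got1$syn, ev1$syn)
  expect_equal(got1$category, ev1$category)
})

test_that("fixation bias drives GC3 to its stationary value", {
  cfg <- sim_config(seed = 24, n_genes = 8, codons_per_gene = 400,
                    B_range = c(2, 2), dfe = dfe_model("GammaZero", shape = 0.4, mean = 1e-4),
                    tree = "((sp1:1.5,sp2:1.5)n1:0.5,sp3:2.0)root;")
  sim <- simulate_alignments(cfg)
  g3 <- mean(vapply(sim$alignments, function(a) gc3(a, "sp1"), numeric(1)))
  expect_equal(g3, exp(2) / (exp(2) + 1), tolerance = 0.03)
})

test_that("count-level SFS means follow theta L / i at neutrality", {
  cfg <- sim_config(seed = 25, theta = 0.02)
  reps <- lapply(1:40, function(r) simulate_sfs_counts(cfg, 1e4, 1e4, seed = 1000 + r))
  avg <- rowMeans(vapply(reps, function(s) s$syn_sfs, numeric(cfg$n_chrom - 1L)))
  expected <- cfg$theta * 1e4 / (1:19)
  expect_equal(avg, expected, tolerance = 0.1)
})

test_that("class distortions scale the observed spectra in expectation", {
  cfg <- sim_config(seed = 26, theta = 0.02)
  ci <- rep(c(1, 2), length.out = 19)
  reps <- lapply(1:40, function(r)
    simulate_sfs_counts(cfg, 1e4, 1e4, distort = ci, seed = 2000 + r))
  avg <- rowMeans(vapply(reps, function(s) s$syn_sfs, numeric(19)))
  expect_equal(avg, cfg$theta * 1e4 / (1:19) * ci, tolerance = 0.12)
})

test_that("gBGC right-shifts the W->S SFS relative to S->W", {
  cfg <- sim_config(seed = 27, n_genes = 60, codons_per_gene = 200,
                    B_range = c(2, 2), theta = 0.02)
  sim <- simulate_alignments(cfg)
  rec <- orient_and_classify(simulate_snps(sim)$snps, sim$alignments, "sp1")
  expect_gt(mean_derived_freq(rec, "WS", syn = TRUE),
            mean_derived_freq(rec, "SW", syn = TRUE))
})

test_that("Marey truth is internally consistent", {
  segs <- data.frame(start_bp = c(0, 5e6), end_bp = c(5e6, 1e7), rate_cM_Mb = c(1, 0))
  sm <- simulate_marey(1e7, segs, n_markers = 100, n_genes = 20, noise_cM = 0, seed = 5)
  expect_equal(sm$total_cM, 5)
  # zero-rate segment: flat genetic positions there
  right <- sm$map$gen_cM[sm$map$phys_bp > 5e6]
  expect_equal(diff(right), rep(0, length(right) - 1))
  # no noise, flat 1 cM/Mb start: exactly linear
  left <- sm$map[sm$map$phys_bp <= 5e6, ]
  expect_equal(left$gen_cM, left$phys_bp / 1e6)
})
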
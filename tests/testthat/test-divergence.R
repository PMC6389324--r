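test_that("single-position substitutions are classified directly", {
  ss <- count_substitutions(pair_alignment("GGG", "GGA"), "anc", "sp1")
  expect_equal(nrow(ss$records), 1L)
  expect_true(ss$records$syn)
  expect_equal(ss$records$category, "SW")
  expect_equal(ss$records$column, 3L)
  expect_equal(ss$records$weight, 1)
  # identical sequences -> empty set
  ss0 <- count_substitutions(pair_alignment("GGG", "GGG"), "anc", "sp1")
  expect_equal(nrow(ss0$records), 0L)
})

test_that("multi-hit codons average over minimal mutational paths", {
  # TTT -> CTC: both orders valid.
  #  via CTT: pos1 nonsyn WS (Phe->Leu), then pos3 syn WS (Leu)
  #  via TTC: pos3 syn WS (Phe), then pos1 nonsyn WS (Phe->Leu)
  ss <- count_substitutions(pair_alignment("TTT", "CTC"), "anc", "sp1")
  r <- ss$records
  expect_equal(sum(r$weight), 2)
  expect_equal(sum(r$weight[r$pos == 1 & !r$syn & r$category == "WS"]), 1)
  expect_equal(sum(r$weight[r$pos == 3 & r$syn & r$category == "WS"]), 1)
})

test_that("paths through stop codons are excluded", {
  # TAC (Tyr) -> TGG (Trp): order pos3-first passes through TAG (stop),
  # so only the pos2-first path (via TGC, Cys) survives
  ss <- count_substitutions(pair_alignment("TAC", "TGG"), "anc", "sp1")
  r <- ss$records
  expect_equal(sum(r$weight), 2)
  expect_equal(r$weight, c(1, 1))
  expect_true(all(!r$syn))
  # A->G is WS, C->G is GC-conservative
  expect_setequal(r$category, c("WS", "CONS"))
})

test_that("excluded codons are skipped", {
  aln <- pair_alignment("GGGAAA", "GGAAAT")
  ss <- count_substitutions(aln, "anc", "sp1", exclude_codons = c(FALSE, TRUE))
  expect_equal(unique(ss$records$codon), 1L)
})

test_that("rate_estimate is a ratio of sums with correct arithmetic", {
  # fabricate two genes: 10 syn subs over 1000 syn sites -> dS = 0.01
  mk_sub <- function(n_syn, n_nonsyn) {
    rec <- data.frame(codon = 1L, pos = 3L, column = 3L, from_base = "G",
                      to_base = "A", syn = rep(c(TRUE, FALSE), c(n_syn, n_nonsyn)),
                      category = "SW", weight = 1)
    structure(list(gene_id = "g", branch = c(parent = "a", child = "b"),
                   records = rec), class = "substitution_set")
  }
  mk_opp <- function(L_syn, L_nonsyn) {
    v <- function(x) stats::setNames(c(0, x, 0, x), c("WS", "SW", "CONS", "ALL"))
    structure(list(gene_id = "g", species = "b", kappa = 1,
                   n_syn = v(L_syn), n_nonsyn = v(L_nonsyn), stop_weight = 0,
                   third = numeric(7)), class = "opportunity_counts")
  }
  subs <- list(mk_sub(4, 2), mk_sub(6, 2))
  opps <- list(mk_opp(400, 100), mk_opp(600, 300))
  re <- rate_estimate(subs, opps, "SW", n_boot = 0)
  expect_equal(re$dS, 10 / 1000)
  expect_equal(re$dN, 4 / 400)
  expect_equal(re$omega, 1)
  # ratio of sums, not mean of per-gene ratios: per-gene omegas are 2.5 and 0.5
  expect_error(rate_estimate(subs, opps, "WS", n_boot = 0), "zero opportunity")
})

test_that("bootstrap is deterministic and degenerates to the point value", {
  ci1 <- bootstrap_ci(10, function(idx) mean(idx), 200, seed = 42)
  ci2 <- bootstrap_ci(10, function(idx) mean(idx), 200, seed = 42)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_ci(10, function(idx) 3.14, 100, seed = 1)
  expect_equal(unname(ci3[1, ]), c(3.14, 3.14))
  expect_error(bootstrap_ci(1, mean, 10), ">= 2 genes")
})

test_that("category rates are additive into the ALL category", {
  sim <- simulate_alignments(tiny_config(seed = 4, B_range = c(0, 2)))
  opps <- lapply(sim$alignments, count_opportunities, species = "sp1", kappa = 2)
  subs <- lapply(sim$alignments, count_substitutions, parent = "n1", child = "sp1")
  res <- lapply(c("ALL", "WS", "SW", "CONS"), function(cat)
    rate_estimate(subs, opps, cat, n_boot = 0))
  names(res) <- c("ALL", "WS", "SW", "CONS")
  dn_all <- res$ALL$dN * res$ALL$L_nonsyn
  dn_sum <- sum(vapply(res[c("WS", "SW", "CONS")],
                       function(r) r$dN * r$L_nonsyn, numeric(1)))
  expect_equal(dn_all, dn_sum, tolerance = 1e-10)
  ds_all <- res$ALL$dS * res$ALL$L_syn
  ds_sum <- sum(vapply(res[c("WS", "SW", "CONS")],
                       function(r) r$dS * r$L_syn, numeric(1)))
  expect_equal(ds_all, ds_sum, tolerance = 1e-10)
})

test_that("gc3_star has the right symmetry, boundaries and scale invariance", {
  mk <- function(ws_sub, sw_sub, ws_opp, sw_opp) {
    cats <- rep(c("WS", "SW"), c(ws_sub, sw_sub))
    nr <- length(cats)
    rec <- data.frame(codon = rep(1L, nr), pos = rep(3L, nr), column = rep(3L, nr),
                      from_base = rep("A", nr), to_base = rep("G", nr),
                      syn = rep(TRUE, nr), category = cats, weight = rep(1, nr))
    sub <- structure(list(gene_id = "g", branch = c(parent = "a", child = "b"),
                          records = rec), class = "substitution_set")
    third <- stats::setNames(numeric(7), c("syn.WS", "syn.SW", "syn.CONS",
                                           "nonsyn.WS", "nonsyn.SW", "nonsyn.CONS", "stop"))
    third["syn.WS"] <- ws_opp; third["syn.SW"] <- sw_opp
    opp <- structure(list(gene_id = "g", species = "b", kappa = 1,
                          n_syn = c(WS = ws_opp, SW = sw_opp, CONS = 0, ALL = ws_opp + sw_opp),
                          n_nonsyn = c(WS = 0, SW = 0, CONS = 0, ALL = 0),
                          stop_weight = 0, third = third),
                     class = "opportunity_counts")
    list(sub = sub, opp = opp)
  }
  eq <- mk(5, 5, 100, 100)
  expect_equal(gc3_star(list(eq$sub), list(eq$opp)), 0.5)
  b1 <- mk(5, 0, 100, 100)
  expect_equal(gc3_star(list(b1$sub), list(b1$opp)), 1)
  # doubling every count leaves GC3* unchanged
  a <- mk(7, 3, 120, 80)
  expect_equal(gc3_star(list(a$sub, a$sub), list(a$opp, a$opp)),
               gc3_star(list(a$sub), list(a$opp)))
  z <- mk(0, 0, 10, 10)
  expect_warning(res <- gc3_star(list(z$sub), list(z$opp)), "undefined")
  expect_true(is.na(res))
})
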
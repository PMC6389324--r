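# Synthetic-data generator with known truth: codon alignments evolved on a
# tree under category-biased fixation (gBGC intensity B on W->S / S->W), a
# Gamma(+adaptive) DFE on nonsynonymous changes, PRF-sampled SNP panels and
# Marey maps. Everything is deterministic under the config seed.

#' Simulation configuration
#'
#' The default values define the canonical synthetic dataset used by the
#' validation suite: 6 taxa, 300 genes of 300 codons, a per-gene gBGC
#' gradient B in \[0, 5\] with root GC3 at the corresponding stationary value
#' `plogis(B)`, kappa = 2, GammaZero deleterious DFE (shape 0.4, mean |S|
#' 2000), no adaptation, theta = 0.02/site, samples of n = 20 chromosomes.
#' Hill-Robertson interference is emulated (not emergent) by scaling the
#' deleterious selection strength in divergence by a per-gene efficacy
#' rising from `hri_min_efficacy` to 1 along the B gradient.
#'
#' @param seed Integer seed; all outputs are byte-identical for a given
#'   config.
#' @param tree Newick string with branch lengths (expected neutral
#'   substitutions/site) and named internal nodes.
#' @param n_genes,codons_per_gene Gene set dimensions.
#' @param kappa Transition/transversion ratio of the mutation process.
#' @param B_range Per-gene scaled gBGC coefficient, linear gradient across
#'   genes (use `c(B, B)` for a constant).
#' @param dfe A [dfe_model()]: the deleterious (and optionally beneficial)
#'   truth DFE of nonsynonymous mutations.
#' @param alpha_true Target fraction of adaptive nonsynonymous
#'   substitutions (at B = 0); implemented as an adaptive site class with
#'   effect `S_adaptive`.
#' @param S_adaptive Scaled effect of adaptive mutations.
#' @param theta Per-site population mutation rate for polymorphism.
#' @param n_chrom Sample size (chromosomes) for SNP panels.
#' @param hri_min_efficacy Selection efficacy of the lowest-recombination
#'   gene (1 = HRI off).
#' @param focal Focal species for polymorphism/divergence (a tip label).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       tree = "((sp1:0.06,sp2:0.08)n1:0.05,((sp3:0.07,sp4:0.05)n2:0.06,(sp5:0.09,sp6:0.11)n3:0.04)n4:0.03)root;",
                       n_genes = 300L, codons_per_gene = 300L, kappa = 2,
                       B_range = c(0, 0), dfe = dfe_model("GammaZero", shape = 0.4, mean = 2000),
                       alpha_true = 0, S_adaptive = 10, theta = 0.02,
                       n_chrom = 20L, hri_min_efficacy = 1, focal = "sp1") {
  structure(list(seed = as.integer(seed), tree = tree, n_genes = as.integer(n_genes),
                 codons_per_gene = as.integer(codons_per_gene), kappa = kappa,
                 B_range = B_range, dfe = dfe, alpha_true = alpha_true,
                 S_adaptive = S_adaptive, theta = theta, n_chrom = as.integer(n_chrom),
                 hri_min_efficacy = hri_min_efficacy, focal = focal),
            class = "sim_config")
}

#' Canonical synthetic configurations
#'
#' The two stated worlds driving the validation experiments:
#' * `"neutral"`: B = 0 everywhere, effectively no selection (Gamma mean
#'   1e-4), no HRI -- the null world where dN/dS = 1 per category and the
#'   synonymous SFS is proportional to 1/i.
#' * `"gradient"`: per-gene gBGC gradient B in 0..5 with matching
#'   stationary root GC3, purifying GammaZero DFE (shape 0.4, mean |S|
#'   2000), no adaptation, and HRI-like loss of selection efficacy in
#'   low-recombination genes (efficacy 0.25 at B = 0 rising to 1 at B = 5,
#'   divergence side).
#'
#' @param variant `"neutral"` or `"gradient"`.
#' @param seed Seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
canonical_config <- function(variant = c("neutral", "gradient"), seed = 1L, ...) {
  variant <- match.arg(variant)
  if (variant == "neutral")
    sim_config(seed = seed, B_range = c(0, 0),
               dfe = dfe_model("GammaZero", shape = 0.4, mean = 1e-4),
               hri_min_efficacy = 1, ...)
  else
    sim_config(seed = seed, B_range = c(0, 5),
               dfe = dfe_model("GammaZero", shape = 0.4, mean = 2000),
               hri_min_efficacy = 0.25, ...)
}

# Adaptive site-class probability giving the target substitution fraction
# alpha_true at B = 0: alpha = p f_a / ((1-p) f_d + p f_a).
adaptive_site_prob <- function(cfg) {
  if (cfg$alpha_true <= 0) return(0)
  f_d <- mean(fixation_factor(gamma_grid(cfg$dfe$shape, cfg$dfe$mean, 512L)))
  f_a <- fixation_factor(cfg$S_adaptive)
  a <- cfg$alpha_true
  a * f_d / (f_a * (1 - a) + a * f_d)
}

# Per-gene truth parameters implied by a config.
gene_truth <- function(cfg) {
  g <- seq_len(cfg$n_genes)
  B <- if (cfg$n_genes == 1L) cfg$B_range[1] else
    seq(cfg$B_range[1], cfg$B_range[2], length.out = cfg$n_genes)
  eff <- if (cfg$n_genes == 1L) 1 else
    cfg$hri_min_efficacy + (1 - cfg$hri_min_efficacy) * (g - 1) / (cfg$n_genes - 1)
  data.frame(gene_id = sprintf("g%04d", g), B = B, efficacy = eff,
             gc3_init = stats::plogis(B), stringsAsFactors = FALSE)
}

# Sample sense codons with target third-position GC (positions 1-2 uniform).
sample_root_codons <- function(n, gc3, rng_unused = NULL) {
  draw <- function(m, p_gc) {
    b1 <- sample.int(4L, m, replace = TRUE)
    b2 <- sample.int(4L, m, replace = TRUE)
    strong <- stats::runif(m) < p_gc
    b3 <- ifelse(strong, sample(c(2L, 3L), m, replace = TRUE),
                 sample(c(1L, 4L), m, replace = TRUE))
    codon_index(b1, b2, b3)
  }
  out <- draw(n, gc3)
  repeat {
    bad <- which(!is_sense_codon_idx(out))
    if (!length(bad)) break
    out[bad] <- draw(length(bad), gc3)
  }
  out
}

# Vectorised per-codon Gillespie along one branch. cod: codon indices;
# t: branch length (expected neutral subs/site, so each position has total
# neutral mutation rate 1); Bv, Sv, effv: per-codon gBGC coefficient,
# selection coefficient of nonsynonymous changes, HRI efficacy.
# Returns list(cod = new codons, events = data.frame).
evolve_branch <- function(cod, t, Bv, Sv, effv, kappa) {
  tab <- change_tables()
  catsign <- matrix(0, 64, 9)
  catsign[tab$CAT == 1L] <- 1
  catsign[tab$CAT == 2L] <- -1
  mutw <- ifelse(tab$TS, kappa, 1) / (kappa + 2) * !tab$STOP
  active <- seq_along(cod)
  trem <- rep(t, length(cod))
  ev <- list()
  while (length(active)) {
    rows <- cod[active]
    W <- mutw[rows, , drop = FALSE]
    Seff <- catsign[rows, , drop = FALSE] * Bv[active] +
      (!tab$SYN[rows, , drop = FALSE]) * (Sv[active] * effv[active])
    rates <- W * matrix(fixation_factor(Seff), nrow(W), 9)
    tot <- rowSums(rates)
    dt <- rep(Inf, length(active))          # codons with zero total rate never move
    pos <- tot > 0
    dt[pos] <- stats::rexp(sum(pos), tot[pos])
    hit <- dt < trem[active]
    if (any(hit)) {
      ai <- active[hit]
      R <- rates[hit, , drop = FALSE]
      u <- stats::runif(length(ai)) * tot[hit]
      jcol <- rep(9L, length(ai))
      acc <- numeric(length(ai)); done <- logical(length(ai))
      for (col in 1:9) {
        acc <- acc + R[, col]
        sel <- !done & u <= acc
        jcol[sel] <- col
        done <- done | sel
      }
      from <- cod[ai]
      id <- cbind(from, jcol)
      ev[[length(ev) + 1L]] <- data.frame(
        codon_global = ai, pos = tab$POS[id],
        from_base = BASES[tab$FROMB[id]], to_base = BASES[tab$TOB[id]],
        syn = tab$SYN[id], category = CATEGORY_LEVELS[tab$CAT[id]],
        stringsAsFactors = FALSE)
      cod[ai] <- tab$TO[id]
      trem[ai] <- trem[ai] - dt[hit]
      active <- ai
    } else active <- integer(0)
  }
  list(cod = cod,
       events = if (length(ev)) do.call(rbind, ev) else
         data.frame(codon_global = integer(), pos = integer(),
                    from_base = character(), to_base = character(),
                    syn = logical(), category = character(),
                    stringsAsFactors = FALSE))
}

#' Simulate a set of codon alignments with true ancestors and substitutions
#'
#' Evolves every gene along the config tree with per-site rates
#' `mutation x kappa-structure x f(S_eff)/f(0)`, where
#' `f(S) = S/(1-exp(-S))` and `S_eff` adds the category's gBGC coefficient
#' (+B for W->S, -B for S->W, 0 for GC-conservative) and, for nonsynonymous
#' changes, the site's selection coefficient drawn from the truth DFE
#' (adaptive with the probability implied by `alpha_true`). Every realised
#' substitution is recorded with its branch: the ground truth for the
#' divergence module.
#'
#' @param cfg A [sim_config()].
#' @return List with `alignments` (named list of [codon_alignment()], all
#'   tips + ancestral nodes), `truth` (per-gene parameters, per-codon
#'   selection coefficients, per-branch event tables), `tree` (ape phylo)
#'   and `config`.
#' @export
simulate_alignments <- function(cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  tree <- ape::read.tree(text = cfg$tree)
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    stop("tree must have named internal nodes")
  gt <- gene_truth(cfg)
  nc <- cfg$codons_per_gene
  N <- cfg$n_genes * nc
  gene_of <- rep(seq_len(cfg$n_genes), each = nc)
  Bv <- gt$B[gene_of]
  effv <- gt$efficacy[gene_of]
  p_adapt <- adaptive_site_prob(cfg)
  adaptive <- stats::runif(N) < p_adapt
  Sv <- ifelse(adaptive, cfg$S_adaptive,
               -stats::rgamma(N, shape = cfg$dfe$shape, scale = cfg$dfe$mean / cfg$dfe$shape))
  root_cod <- integer(N)
  for (g in seq_len(cfg$n_genes))
    root_cod[gene_of == g] <- sample_root_codons(nc, gt$gc3_init[g])
  labels <- c(tree$tip.label, tree$node.label)
  root_label <- labels[ape::Ntip(tree) + 1L]
  seqs <- list()
  seqs[[root_label]] <- root_cod
  br <- tree_branches(tree)
  events <- list()
  todo <- seq_len(nrow(br))
  while (length(todo)) {
    ready <- todo[br$parent[todo] %in% names(seqs)]
    k <- ready[1]
    res <- evolve_branch(seqs[[br$parent[k]]], br$length[k], Bv, Sv, effv, cfg$kappa)
    seqs[[br$child[k]]] <- res$cod
    if (nrow(res$events)) res$events$branch <- br$child[k]
    events[[br$child[k]]] <- res$events
    todo <- setdiff(todo, k)
  }
  # assemble per-gene alignments
  alignments <- vector("list", cfg$n_genes)
  names(alignments) <- gt$gene_id
  tips <- tree$tip.label
  nodes <- tree$node.label
  for (g in seq_len(cfg$n_genes)) {
    idx <- which(gene_of == g)
    mk <- function(nm) {
      b <- codon_bases_vec(seqs[[nm]][idx])
      as.integer(b)
    }
    sq <- lapply(c(tips, nodes), mk)
    names(sq) <- c(tips, nodes)
    alignments[[g]] <- structure(
      list(gene_id = gt$gene_id[g], seqs = sq, tips = tips, nodes = nodes,
           tree = tree, n_sites = 3L * nc),
      class = "codon_alignment")
  }
  ev <- do.call(rbind, events[vapply(events, nrow, integer(1)) > 0])
  if (!is.null(ev)) {
    ev$gene_id <- gt$gene_id[gene_of[ev$codon_global]]
    ev$codon <- (ev$codon_global - 1L) %% nc + 1L
    ev$column <- (ev$codon - 1L) * 3L + ev$pos
  }
  list(alignments = alignments,
       truth = list(genes = gt, S_sel = Sv, adaptive = adaptive,
                    p_adapt = p_adapt, events = ev, gene_of = gene_of),
       tree = tree, config = cfg)
}

# Interleave codon indices into a nucleotide integer vector.
codon_bases_vec <- function(idx) {
  i <- idx - 1L
  rbind(i %/% 16L + 1L, (i %/% 4L) %% 4L + 1L, i %% 4L + 1L)
}

# --- PRF class-count machinery (generator side) -----------------------------
# Midpoint-rule integrals on a fine grid, tabulated over S and interpolated
# by nearest log-|S| node: deliberately a different numerical route from the
# fitter's Gauss-Legendre quadrature.
prf_table <- function(n, m_grid = 4000L) {
  key <- paste0("prf", n)
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  Sneg <- -exp(seq(log(1e-3), log(5e4), length.out = 160L))
  Spos <- exp(seq(log(1e-3), log(500), length.out = 80L))
  Sgrid <- c(sort(Sneg), 0, Spos)
  x <- (seq_len(m_grid) - 0.5) / m_grid
  lx <- log(x); l1x <- log1p(-x)
  P <- matrix(0, length(Sgrid), n - 1L)
  for (k in seq_along(Sgrid)) {
    hr <- sojourn_ratio(Sgrid[k], x)
    for (i in seq_len(n - 1L))
      P[k, i] <- sum(hr * exp(lchoose(n, i) + (i - 1) * lx + (n - i - 1) * l1x)) / m_grid
  }
  res <- list(S = Sgrid, P = P, T = rowSums(P))
  .codon_cache[[key]] <- res
  res
}

prf_lookup <- function(S, n) {
  tb <- prf_table(n)
  idx <- vapply(S, function(s) which.min(abs(tb$S - s)), integer(1))
  list(P = tb$P[idx, , drop = FALSE], T = tb$T[idx])
}

#' Simulate SNP panels for a simulated alignment set
#'
#' Places SNPs on the focal species' gene sequences by Poisson sampling from
#' the PRF: for each candidate single-base change (at codons identical
#' between the focal tip and its parent node, so ancestral truth is
#' unambiguous), the expected number of segregating sites is
#' `theta x weight x T(S_eff)` where T sums the expected unfolded SFS over
#' frequency classes, and `S_eff` combines the gene's gBGC coefficient
#' (by category) with the codon's selection coefficient for nonsynonymous
#' changes. Derived counts are drawn from the per-class PRF probabilities.
#'
#' @param sim Output of [simulate_alignments()].
#' @param distort Optional length n-1 vector of class multipliers c_i
#'   applied to both synonymous and nonsynonymous spectra (for nuisance
#'   r_i recovery tests).
#' @param seed Seed (default: config seed + 1).
#' @return List with `snps`: raw SNP table (`gene_id`, `column`, `allele1`,
#'   `allele2`, `count1`, `count2`, allele order randomised) and `truth`:
#'   data frame of the generating records (ancestral/derived, category,
#'   syn, derived count).
#' @export
simulate_snps <- function(sim, distort = NULL, seed = NULL) {
  cfg <- sim$config
  n <- cfg$n_chrom
  if (is.null(distort)) distort <- rep(1, n - 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  tab <- change_tables()
  tree <- sim$tree
  par_lab <- parent_node(tree, cfg$focal)
  gt <- sim$truth$genes
  out <- list()
  truth <- list()
  for (g in seq_len(nrow(gt))) {
    aln <- sim$alignments[[g]]
    cp <- codon_indices(aln, par_lab)
    cc <- codon_indices(aln, cfg$focal)
    ok <- which(!is.na(cp) & !is.na(cc) & cp == cc)
    if (!length(ok)) next
    codons <- cp[ok]
    gene_rows <- rep(ok, each = 9L)
    j <- rep(1:9, times = length(ok))
    id <- cbind(rep(codons, each = 9L), j)
    keep <- !tab$STOP[id]
    w <- (ifelse(tab$TS[id], cfg$kappa, 1) / (cfg$kappa + 2))[keep]
    cat_i <- tab$CAT[id][keep]
    syn_i <- tab$SYN[id][keep]
    pos_i <- tab$POS[id][keep]
    codon_k <- gene_rows[keep]
    from_b <- tab$FROMB[id][keep]
    to_b <- tab$TOB[id][keep]
    Bcat <- c(1, -1, 0)[cat_i] * gt$B[g]
    codon_global <- (g - 1L) * cfg$codons_per_gene + codon_k
    Seff <- Bcat + ifelse(syn_i, 0, sim$truth$S_sel[codon_global])
    lk <- prf_lookup(Seff, n)
    Pd <- lk$P * matrix(distort, nrow(lk$P), n - 1L, byrow = TRUE)
    Td <- rowSums(Pd)
    mu <- cfg$theta * w * Td
    n_snp <- stats::rpois(length(mu), mu)
    hits <- which(n_snp > 0)
    if (!length(hits)) next
    hits <- rep(hits, n_snp[hits])  # multiple SNPs at one site collapse below
    col <- (codon_k[hits] - 1L) * 3L + pos_i[hits]
    dup <- duplicated(col)
    hits <- hits[!dup]; col <- col[!dup]
    dc <- vapply(hits, function(h) sample.int(n - 1L, 1L, prob = Pd[h, ]), integer(1))
    anc <- BASES[from_b[hits]]
    der <- BASES[to_b[hits]]
    swap <- stats::runif(length(hits)) < 0.5
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = gt$gene_id[g], column = col, ancestral = anc, derived = der,
      derived_count = dc, n = n, syn = syn_i[hits],
      category = CATEGORY_LEVELS[cat_i[hits]], stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gt$gene_id[g], column = col,
      allele1 = ifelse(swap, der, anc), allele2 = ifelse(swap, anc, der),
      count1 = ifelse(swap, dc, n - dc), count2 = ifelse(swap, n - dc, dc),
      stringsAsFactors = FALSE)
  }
  list(snps = if (length(out)) do.call(rbind, out) else NULL,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Fast count-level SFS simulation
#'
#' Draws an `sfs_pair` directly at the frequency-class level (no sequences):
#' synonymous class means `theta L_syn phi_i(B) c_i`, nonsynonymous class
#' means `theta L_nonsyn E_S[phi_i(B + S)] c_i` with S from the truth DFE
#' (quantile-grid expectation over the generator's midpoint-rule PRF table).
#' Used for estimator-recovery experiments at scale.
#'
#' @param cfg A [sim_config()] (uses theta, dfe, n_chrom, kappa-independent
#'   site totals are passed explicitly).
#' @param L_syn,L_nonsyn Opportunity totals.
#' @param B gBGC coefficient applied (+B syn and nonsyn W->S-like shift; 0
#'   for a category-free experiment).
#' @param distort Optional class multipliers c_i.
#' @param D Optional divergence counts list(D_syn, D_nonsyn) to attach.
#' @param seed Seed.
#' @param category Category label stored on the pair.
#' @return An `sfs_pair`.
#' @export
simulate_sfs_counts <- function(cfg, L_syn, L_nonsyn, B = 0, distort = NULL,
                                D = NULL, seed = cfg$seed, category = "ALL") {
  n <- cfg$n_chrom
  if (is.null(distort)) distort <- rep(1, n - 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  syn_mean <- cfg$theta * L_syn * prf_lookup(B, n)$P[1, ] * distort
  K <- 64L
  Sdel <- B + gamma_grid(cfg$dfe$shape, cfg$dfe$mean, K)
  Pdel <- prf_lookup(Sdel, n)$P
  # deleterious DFE only: the adaptive class of alpha_true is a
  # divergence-side injection (see simulate_divergence_counts)
  psi <- colMeans(Pdel)
  nonsyn_mean <- cfg$theta * L_nonsyn * psi * distort
  structure(list(category = category, n = n,
                 syn_sfs = stats::rpois(n - 1L, syn_mean),
                 nonsyn_sfs = stats::rpois(n - 1L, nonsyn_mean),
                 L_syn = L_syn, L_nonsyn = L_nonsyn,
                 D_syn = if (is.null(D)) NA_real_ else D$D_syn,
                 D_nonsyn = if (is.null(D)) NA_real_ else D$D_nonsyn),
            class = "sfs_pair")
}

#' Fast count-level divergence simulation
#'
#' Poisson substitution counts on a branch of length `t` (expected neutral
#' substitutions/site): synonymous mean `L_syn t f(B)`, nonsynonymous mean
#' `L_nonsyn t ((1-p) E[f(B+S)] + p f(B+S_adaptive))` with S from the truth
#' DFE and p the adaptive site probability implied by `alpha_true`.
#'
#' @param cfg A [sim_config()].
#' @param L_syn,L_nonsyn Site totals.
#' @param t Branch length.
#' @param B gBGC coefficient.
#' @param seed Seed.
#' @return List with `D_syn`, `D_nonsyn`, and the deterministic expected
#'   rates `rate_syn`, `rate_nonsyn` (per site).
#' @export
simulate_divergence_counts <- function(cfg, L_syn, L_nonsyn, t, B = 0, seed = cfg$seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f_syn <- fixation_factor(B)
  Sdel <- B + gamma_grid(cfg$dfe$shape, cfg$dfe$mean, 512L)
  p <- adaptive_site_prob(cfg)
  f_nonsyn <- (1 - p) * mean(fixation_factor(Sdel)) +
    p * fixation_factor(B + cfg$S_adaptive)
  list(D_syn = stats::rpois(1, L_syn * t * f_syn),
       D_nonsyn = stats::rpois(1, L_nonsyn * t * f_nonsyn),
       rate_syn = t * f_syn, rate_nonsyn = t * f_nonsyn)
}

#' Simulate a Marey map with known per-gene recombination truth
#'
#' Genetic position is the integral of a piecewise-constant true rate along
#' the chromosome, observed at marker positions with Gaussian noise; genes
#' are random intervals with the true rate taken at their midpoint.
#'
#' @param length_bp Chromosome length.
#' @param segments Data frame `start_bp`, `end_bp`, `rate_cM_Mb` covering
#'   \[0, length_bp\].
#' @param n_markers,n_genes Numbers of markers and genes.
#' @param noise_cM SD of marker noise in cM.
#' @param seed Seed.
#' @return List with `map` (`chrom`, `marker_id`, `phys_bp`, `gen_cM`),
#'   `genes` (`gene_id`, `start_bp`, `end_bp`, `true_rate`), and
#'   `total_cM`.
#' @export
simulate_marey <- function(length_bp, segments, n_markers = 500L, n_genes = 100L,
                           noise_cM = 0.05, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gen_at <- function(x) {
    vapply(x, function(p) {
      sum(pmax(pmin(p, segments$end_bp) - segments$start_bp, 0) / 1e6 * segments$rate_cM_Mb)
    }, numeric(1))
  }
  rate_at <- function(x) {
    vapply(x, function(p) {
      segments$rate_cM_Mb[which(p >= segments$start_bp & p < segments$end_bp)[1]]
    }, numeric(1))
  }
  pos <- sort(stats::runif(n_markers, 0, length_bp))
  gen <- gen_at(pos) + stats::rnorm(n_markers, 0, noise_cM)
  gstart <- stats::runif(n_genes, 0.02 * length_bp, 0.95 * length_bp)
  glen <- stats::runif(n_genes, 1e3, 2e4)
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      start_bp = gstart, end_bp = gstart + glen,
                      true_rate = rate_at(gstart + glen / 2),
                      stringsAsFactors = FALSE)
  list(map = data.frame(chrom = "chr1", marker_id = sprintf("m%04d", seq_len(n_markers)),
                        phys_bp = pos, gen_cM = gen, stringsAsFactors = FALSE),
       genes = genes, total_cM = gen_at(length_bp))
}
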
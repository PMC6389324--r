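# End-to-end orchestration: simulate (or ingest) -> opportunities ->
# divergence -> polymorphism -> bins -> DFE-alpha, with TSV outputs and a
# reproducibility manifest.

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: data simulation (or ingestion), kappa
#' estimation, opportunity counting, per-branch substitution counting on the
#' focal terminal branch (excluding codons polymorphic in the focal
#' species), SNP orientation, GC3 binning with divergence correlation
#' tables, per-category SFS construction and DFE-alpha fitting. Each stage
#' writes a TSV (or SFS text file) into `outdir`; a JSON manifest records
#' the config, seed and MD5 checksums of every output, so a rerun with the
#' same config is byte-identical.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param k_bins Number of GC3 bins for the divergence table.
#' @param mask_cpg Mask CpG-containing columns before any counting.
#' @param model DFE model name for the fits.
#' @param categories Categories analysed with the DFE.
#' @param n_boot Bootstrap replicates for pooled divergence CIs.
#' @return Invisibly, a list with the main in-memory results (`kappa`,
#'   `rates`, `bin_table`, `dfe` per category, `dropped` SNP counts,
#'   `files`).
#' @export
run_pipeline <- function(cfg, outdir, k_bins = 10L, mask_cpg = FALSE,
                         model = "GammaZero", categories = c("ALL", CATEGORY_LEVELS),
                         n_boot = 1000L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("simulating %d genes x %d codons (seed %d)", cfg$n_genes, cfg$codons_per_gene, cfg$seed)
  sim <- simulate_alignments(cfg)
  snp_raw <- simulate_snps(sim)
  alns <- sim$alignments
  if (mask_cpg) {
    alns <- lapply(alns, mask_cpg_columns)
    say("CpG masking: %s columns masked on average",
        format(mean(vapply(alns, function(a) attr(a, "n_masked_columns"), numeric(1))), digits = 3))
  }
  focal <- cfg$focal
  tree <- sim$tree
  par_lab <- parent_node(tree, focal)

  kappa_hat <- estimate_kappa(alns)
  say("kappa estimate: %.3f", kappa_hat)

  snp_rec <- orient_and_classify(snp_raw$snps, alns, focal)
  say("SNPs: %d retained; dropped: %s", nrow(snp_rec$records),
      paste(names(snp_rec$dropped), snp_rec$dropped, sep = "=", collapse = ", "))

  # codons polymorphic in the focal species are excluded from its branch
  poly_excl <- lapply(alns, function(a) {
    rec <- snp_rec$records[snp_rec$records$gene_id == a$gene_id, ]
    excl <- logical(a$n_sites / 3L)
    excl[unique(rec$codon)] <- TRUE
    excl
  })
  opps <- lapply(alns, count_opportunities, species = focal, kappa = kappa_hat)
  subs <- lapply(names(alns), function(g)
    count_substitutions(alns[[g]], par_lab, focal, exclude_codons = poly_excl[[g]]))
  names(subs) <- names(alns)
  write_opportunities(opps, file.path(outdir, "opportunities.tsv"))

  gene_tab <- data.frame(
    gene_id = names(alns),
    gc3 = vapply(alns, function(a) gc3(a, focal), numeric(1)),
    n_snps = as.integer(table(factor(snp_rec$records$gene_id, levels = names(alns)))),
    stringsAsFactors = FALSE)
  utils::write.table(gene_tab, file.path(outdir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rates <- lapply(categories, function(cat)
    rate_estimate(subs, opps, category = cat, n_boot = n_boot, seed = cfg$seed))
  names(rates) <- categories
  rate_df <- do.call(rbind, lapply(rates, function(r)
    data.frame(category = r$category, dN = r$dN, dS = r$dS, omega = r$omega,
               omega_low = if (!is.null(r$ci)) r$ci["omega", "low"] else NA,
               omega_high = if (!is.null(r$ci)) r$ci["omega", "high"] else NA)))
  utils::write.table(rate_df, file.path(outdir, "divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("pooled dN/dS (ALL): %.4f", rates[["ALL"]]$omega)

  gc3_key <- stats::setNames(gene_tab$gc3, gene_tab$gene_id)
  binning <- make_bins(gene_tab$gene_id, gene_tab$gc3, k = k_bins)
  btab <- bin_divergence_table(binning, gc3_key, subs, opps, categories = categories)
  utils::write.table(btab$per_bin, file.path(outdir, "bins_divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(btab$correlations, file.path(outdir, "bins_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  dfe_rows <- list()
  fits <- list()
  for (cat in categories) {
    sfs <- build_sfs(snp_rec, opps, subs, category = cat, n = cfg$n_chrom)
    write_sfs(sfs, file.path(outdir, sprintf("sfs_%s.txt", cat)))
    fit <- fit_dfe(sfs, model = model, seed = cfg$seed)
    ao <- alpha_omega(fit)
    fits[[cat]] <- list(fit = fit, ao = ao)
    dfe_rows[[cat]] <- data.frame(
      category = cat, model = fit$model$name, shape = fit$model$shape,
      mean_S = fit$model$mean, p_pos = fit$model$p_pos, theta = fit$theta,
      loglik = fit$loglik, converged = fit$convergence == 0,
      dnds_obs = ao$dnds_obs, alpha = ao$alpha, omega_a = ao$omega_a,
      omega_na = ao$omega_na, stringsAsFactors = FALSE)
    say("DFE %s [%s]: shape=%.3f alpha=%.3f omega_a=%.4f", model, cat,
        fit$model$shape, ao$alpha, ao$omega_a)
  }
  utils::write.table(do.call(rbind, dfe_rows), file.path(outdir, "dfe_alpha.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("gbgctools")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "dfe")],
    dfe_truth = unclass(cfg$dfe),
    outputs = as.list(stats::setNames(unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(kappa = kappa_hat, rates = rates, bin_table = btab,
                 dfe = fits, dropped = snp_rec$dropped,
                 files = file.path(outdir, files)))
}
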
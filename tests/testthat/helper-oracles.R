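# Independent oracles and tiny fixtures shared across tests.

BASES4 <- c("A", "C", "G", "T")

# Amino acid of a codon via Biostrings::translate -- an independent code
# path from the package's lookup tables (cached for speed).
.aa_cache <- local({
  all64 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                           c("A", "C", "G", "T"), paste0))
  stats::setNames(as.character(Biostrings::translate(Biostrings::DNAStringSet(all64),
                                                     no.init.codon = TRUE,
                                                     if.fuzzy.codon = "error")), all64)
})
oracle_translate <- function(codon) unname(.aa_cache[codon])

# All 61 sense codons.
sense_codons <- function() {
  all64 <- as.vector(outer(outer(BASES4, BASES4, paste0), BASES4, paste0))
  all64[oracle_translate(all64) != "*"]
}

# Brute-force site weights of one codon: enumerate the 9 single-base
# changes, weight kappa (transition) / 1 (transversion) normalised per
# position, attribute to syn/nonsyn x category, drop stop-producing changes.
oracle_site_weights <- function(codon, kappa) {
  b <- strsplit(codon, "")[[1]]
  aa0 <- oracle_translate(codon)
  syn <- nonsyn <- c(WS = 0, SW = 0, CONS = 0)
  stop_w <- 0
  is_transition <- function(x, y) paste0(sort(c(x, y)), collapse = "") %in% c("AG", "CT")
  for (p in 1:3) for (a in setdiff(BASES4, b[p])) {
    w <- (if (is_transition(b[p], a)) kappa else 1) / (kappa + 2)
    nb <- b; nb[p] <- a
    aa1 <- oracle_translate(paste(nb, collapse = ""))
    if (aa1 == "*") { stop_w <- stop_w + w; next }
    weak <- c("A", "T")
    cat <- if (b[p] %in% weak && !(a %in% weak)) "WS"
           else if (!(b[p] %in% weak) && a %in% weak) "SW" else "CONS"
    if (aa1 == aa0) syn[cat] <- syn[cat] + w else nonsyn[cat] <- nonsyn[cat] + w
  }
  list(syn = syn, nonsyn = nonsyn, stop_weight = stop_w)
}

# Two-taxon alignment fixture with explicit parent ("anc") sequence.
pair_alignment <- function(parent, child, gene_id = "g1") {
  tr <- ape::read.tree(text = "(sp1:0.1,sp2:0.1)anc;")
  codon_alignment(gene_id, c(sp1 = child, sp2 = parent), c(anc = parent), tr)
}

# Small deterministic configs for simulation-backed tests.
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 30L, codons_per_gene = 120L, ...)
}
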
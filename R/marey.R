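# Marey-map recombination rates: local-linear (loess-style) smoothing of
# genetic position against physical position; the local slope at a gene's
# midpoint is its recombination rate in cM/Mb.

#' Clean a Marey map of non-monotone markers
#'
#' Keeps the longest nondecreasing subsequence of genetic positions (markers
#' in physical order); discarded markers are reported in the
#' `removed` attribute.
#'
#' @param map Data frame with columns `phys_bp` and `gen_cM` (extra columns
#'   kept).
#' @return The cleaned, physically sorted map.
#' @export
clean_marey_map <- function(map) {
  map <- map[order(map$phys_bp), , drop = FALSE]
  g <- map$gen_cM
  n <- length(g)
  if (n == 0L) return(map)
  # O(n log n) longest nondecreasing subsequence with parent links
  tails <- integer(0)   # indices of subsequence tails
  parent <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {             # first tail with value > g[i]
      mid <- (lo + hi) %/% 2L
      if (g[tails[mid]] > g[i]) hi <- mid else lo <- mid + 1L
    }
    parent[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  keep <- integer(0)
  k <- tails[length(tails)]
  while (k > 0L) { keep <- c(k, keep); k <- parent[k] }
  out <- map[keep, , drop = FALSE]
  attr(out, "removed") <- nrow(map) - length(keep)
  out
}

#' Fit a loess-style Marey map
#'
#' Local-linear regression of genetic position (cM) on physical position
#' (bp) with tricube weights and a nearest-neighbour span (default 0.2, the
#' standard Marey-map setting). The local slope of the fit -- obtained
#' analytically from the weighted linear regression at the evaluation point,
#' not by finite differences -- is the recombination rate.
#'
#' @param map Data frame with `phys_bp`, `gen_cM` (cleaned with
#'   [clean_marey_map()] beforehand; done internally otherwise).
#' @param span Fraction of markers in each local window.
#' @param min_markers Minimum markers required (default 5).
#' @return Object of class `marey_fit` with `predict(x)` and `slope(x)`
#'   functions (cM and cM/bp) plus the marker range.
#' @export
fit_marey <- function(map, span = 0.2, min_markers = 5L) {
  map <- clean_marey_map(map)
  x <- as.numeric(map$phys_bp); y <- as.numeric(map$gen_cM)
  n <- length(x)
  if (n < min_markers) stop("fewer than ", min_markers, " usable markers")
  k <- max(2L, ceiling(span * n))
  local_fit <- function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = k)[k]
    if (h == 0) h <- max(d[d > 0][1], 1)  # coincident markers fallback
    w <- (1 - pmin(d / h, 1)^3)^3
    sw <- sum(w)
    xm <- sum(w * x) / sw; ym <- sum(w * y) / sw
    sxx <- sum(w * (x - xm)^2)
    b <- if (sxx > 0) sum(w * (x - xm) * (y - ym)) / sxx else 0
    c(intercept = ym - b * xm, slope = b)
  }
  structure(list(
    predict = function(x0) vapply(x0, function(z) { f <- local_fit(z); f[1] + f[2] * z }, numeric(1)),
    slope = function(x0) vapply(x0, function(z) local_fit(z)[2], numeric(1)),
    range = range(x), n_markers = n,
    removed = attr(map, "removed")), class = "marey_fit")
}

#' Per-gene recombination rate from a Marey fit
#'
#' Rate r = d(cM)/d(bp) at the gene midpoint, scaled to cM/Mb; negative
#' local slopes are clamped to 0 (flagged in the `clamped` column). Genes
#' whose midpoint falls outside the marker range get `NA`.
#'
#' @param fit A `marey_fit`.
#' @param genes Data frame with `gene_id`, `start_bp`, `end_bp` (0-based
#'   half-open, BED-style).
#' @return Data frame `gene_id`, `midpoint_bp`, `rate_cM_Mb`, `clamped`.
#' @export
gene_rate <- function(fit, genes) {
  mid <- (genes$start_bp + genes$end_bp) / 2
  inside <- mid >= fit$range[1] & mid <= fit$range[2]
  r <- rep(NA_real_, length(mid))
  r[inside] <- fit$slope(mid[inside]) * 1e6
  clamped <- !is.na(r) & r < 0
  r[clamped] <- 0
  data.frame(gene_id = genes$gene_id, midpoint_bp = mid,
             rate_cM_Mb = r, clamped = clamped, stringsAsFactors = FALSE)
}

#' Total genetic length recovered by a Marey fit
#'
#' Integral of the clamped slope over the marker range (trapezoid on a fine
#' grid); on a clean map this should be close to the raw last-minus-first
#' genetic position.
#'
#' @param fit A `marey_fit`.
#' @param n_grid Grid resolution.
#' @return Length in cM.
#' @export
marey_map_length <- function(fit, n_grid = 2000L) {
  xs <- seq(fit$range[1], fit$range[2], length.out = n_grid)
  sl <- pmax(fit$slope(xs), 0)
  sum((sl[-1] + sl[-n_grid]) / 2 * diff(xs))
}
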
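# Windowed protection score (WPS) nucleosome footprinting around TSSs:
# mononucleosomal filter, per-position window counting, mean adjustment,
# Gaussian smoothing, gene-set aggregation.

#' Keep mononucleosomal fragments
#'
#' Retains fragments with 120 <= length <= 200 bp (inclusive), the size
#' band used for nucleosome footprinting.
#'
#' @param fragments a GRanges.
#' @param minLen,maxLen inclusive bounds in bp.
#' @return the filtered GRanges.
#' @export
filterMononucleosomal <- function(fragments, minLen = 120L, maxLen = 200L) {
  w <- GenomicRanges::width(fragments)
  fragments[w >= minLen & w <= maxLen]
}

#' Raw windowed protection score across a TSS span
#'
#' For every position p in `[tss - flank, tss + flank)` a window
#' `[p - w/2, p + w/2)` (0-based half-open, centred on p) is evaluated:
#' the score is the number of fragments fully spanning the window minus
#' the number with at least one endpoint strictly inside it. A fragment
#' whose start coincides with the window start is spanning-compatible, not
#' an interior endpoint; fragments entirely outside the window contribute
#' nothing. Computed in O(F + P) with difference arrays.
#'
#' @param fragments a GRanges, normally pre-filtered with
#'   [filterMononucleosomal()].
#' @param tss TSS position, 0-based bp.
#' @param chrom optional chromosome name to subset fragments.
#' @param window window width in bp (even; default 120).
#' @param flank half-span in bp (default 2500, i.e. a 5-kb region).
#' @return integer vector of length 2*flank named by signed distance from
#'   the TSS (genome orientation; see [geneWpsProfile()] for strand
#'   orientation).
#' @export
rawWps <- function(fragments, tss, chrom = NULL, window = 120L,
                   flank = 2500L) {
  window <- as.integer(window); flank <- as.integer(flank)
  if (window %% 2L != 0L) stop("window width must be even")
  if (window > 2L * flank) stop("window larger than the span")
  h <- window %/% 2L
  P0 <- as.integer(tss) - flank
  P1 <- as.integer(tss) + flank - 1L
  P <- 2L * flank
  if (!is.null(chrom))
    fragments <- fragments[
      as.character(GenomicRanges::seqnames(fragments)) == chrom]
  s <- GenomicRanges::start(fragments) - 1L # 0-based half-open
  e <- GenomicRanges::end(fragments)
  near <- e >= P0 - h & s <= P1 + h
  s <- s[near]; e <- e[near]
  diffOf <- function(a, b) {
    # +1 on positions [a, b] (clipped to the span), as a difference array
    a <- pmax(a, P0); b <- pmin(b, P1)
    ok <- a <= b
    tabulate(a[ok] - P0 + 1L, nbins = P + 1L) -
      tabulate(b[ok] - P0 + 2L, nbins = P + 1L)
  }
  dd <- diffOf(s + h, e - (window - h)) # fully spanning
  len <- e - s
  short <- len <= window - 1L # endpoint intervals merge
  dd <- dd - diffOf(s[short] - (window - h) + 1L, e[short] + h - 1L)
  dd <- dd - diffOf(s[!short] - (window - h) + 1L, s[!short] + h - 1L)
  dd <- dd - diffOf(e[!short] - (window - h) + 1L, e[!short] + h - 1L)
  score <- cumsum(dd)[seq_len(P)]
  names(score) <- (P0:P1) - as.integer(tss)
  score
}

#' Mean-adjust and Gaussian-smooth a raw WPS track
#'
#' The adjusted track subtracts the span mean (coverage adjustment); the
#' smoothed track convolves it with a Gaussian kernel of SD `bandwidth`
#' bp, truncated at +/- `truncate` SDs and renormalised over the available
#' support at the edges.
#'
#' @param raw numeric raw WPS over the span.
#' @param bandwidth kernel SD in bp (default 30).
#' @param truncate kernel truncation in SDs (default 4).
#' @return list with `adjusted` and `smoothed` numeric vectors.
#' @export
adjustAndSmooth <- function(raw, bandwidth = 30, truncate = 4) {
  n <- length(raw)
  adjusted <- raw - mean(raw)
  K <- as.integer(ceiling(bandwidth * truncate))
  kern <- stats::dnorm(-K:K, sd = bandwidth)
  kern <- kern / sum(kern)
  pad <- rep(0, K)
  num <- stats::filter(c(pad, adjusted, pad), kern, sides = 2)
  den <- stats::filter(c(pad, rep(1, n), pad), kern, sides = 2)
  smoothed <- as.numeric(num)[(K + 1):(K + n)] /
    as.numeric(den)[(K + 1):(K + n)]
  list(adjusted = unname(adjusted), smoothed = smoothed)
}

#' Per-gene WPS profile, transcription-oriented
#'
#' Computes the raw WPS over the 5-kb span centred on the gene's TSS,
#' mirrors minus-strand genes so positive distances point downstream in
#' the direction of transcription, then mean-adjusts and smooths.
#'
#' @param fragments a GRanges of mononucleosomal fragments.
#' @param tss TSS position, 0-based bp.
#' @param strand "+" or "-".
#' @param chrom optional chromosome subset.
#' @param window,flank,bandwidth see [rawWps()] and [adjustAndSmooth()].
#' @return a [WpsProfile-class] with nGenes = 1.
#' @export
geneWpsProfile <- function(fragments, tss, strand = "+", chrom = NULL,
                           window = 120L, flank = 2500L, bandwidth = 30) {
  raw <- rawWps(fragments, tss, chrom = chrom, window = window,
                flank = flank)
  if (strand == "-") raw <- rev(raw)
  asm <- adjustAndSmooth(raw, bandwidth = bandwidth)
  grid <- as.integer(seq(-flank, flank - 1L))
  new("WpsProfile", distance = grid, raw = unname(as.numeric(raw)),
      adjusted = asm$adjusted, smoothed = asm$smoothed, nGenes = 1L,
      ciLow = rep(NA_real_, length(grid)),
      ciHigh = rep(NA_real_, length(grid)))
}

#' Average per-gene profiles over a gene set
#'
#' Per-distance mean of the smoothed per-gene tracks with a 95% confidence
#' band (mean +/- 1.96 SE across genes).
#'
#' @param profiles list of [WpsProfile-class] objects on identical grids.
#' @return an aggregated [WpsProfile-class].
#' @export
aggregateGeneSet <- function(profiles) {
  if (length(profiles) == 0L) stop("empty gene set")
  grid <- wpsDistance(profiles[[1]])
  mat <- do.call(rbind, lapply(profiles, wpsSmoothed))
  adjMat <- do.call(rbind, lapply(profiles, wpsAdjusted))
  m <- colMeans(mat)
  nG <- nrow(mat)
  se <- if (nG > 1) apply(mat, 2, stats::sd) / sqrt(nG) else rep(0, ncol(mat))
  new("WpsProfile", distance = grid, raw = rep(NA_real_, length(grid)),
      adjusted = colMeans(adjMat), smoothed = m, nGenes = as.integer(nG),
      ciLow = m - 1.96 * se, ciHigh = m + 1.96 * se)
}

#' End-to-end gene-set WPS profile from fragments
#'
#' Applies the mononucleosomal filter, computes a per-gene adjusted and
#' smoothed profile for every gene in the table (dropping genes with no
#' fragment near their span; the count of genes retained is recorded in
#' the result), and averages across genes.
#'
#' @param fragments a GRanges (unfiltered; the 120-200 bp filter is
#'   applied here).
#' @param genes data.frame with columns gene_id, chrom, tss, strand (as
#'   from [generateGenes()]).
#' @param window,flank,bandwidth see [rawWps()] / [adjustAndSmooth()].
#' @param monoRange inclusive fragment-length bounds of the
#'   mononucleosomal filter.
#' @param perGene if TRUE, also return the per-gene profiles.
#' @return an aggregated [WpsProfile-class]; with `perGene = TRUE`, a list
#'   with elements `aggregate` and `profiles`.
#' @export
wpsGeneSetProfile <- function(fragments, genes, window = 120L,
                              flank = 2500L, bandwidth = 30,
                              monoRange = c(120L, 200L), perGene = FALSE) {
  if (nrow(genes) == 0L) stop("empty gene set")
  mono <- filterMononucleosomal(fragments, monoRange[1], monoRange[2])
  pad <- window + 800L
  regions <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, genes$tss - flank - pad),
                              end = genes$tss + flank + pad))
  hits <- GenomicRanges::findOverlaps(regions, mono)
  byGene <- split(S4Vectors::subjectHits(hits),
                  factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(genes))))
  profs <- list()
  for (i in seq_len(nrow(genes))) {
    idx <- byGene[[i]]
    if (length(idx) == 0L) next # gene with no informative fragments
    profs[[genes$gene_id[i]]] <- geneWpsProfile(
      mono[idx], tss = genes$tss[i], strand = genes$strand[i],
      chrom = genes$chrom[i], window = window, flank = flank,
      bandwidth = bandwidth)
  }
  if (length(profs) == 0L) stop("no gene had fragments near its span")
  agg <- aggregateGeneSet(profs)
  if (perGene) list(aggregate = agg, profiles = profs) else agg
}

#' Write an aggregated profile as TSV
#'
#' @param profile a [WpsProfile-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
  df <- data.frame(d = wpsDistance(profile),
                   mean = wpsSmoothed(profile),
                   ci_low = profile@ciLow, ci_high = profile@ciHigh,
                   n_genes = nGenes(profile))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
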
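# Oriented fragment end-motif extraction, observed and genome-expected
# frequencies, differential usage and covariate correlation.

.MOTIF_SUPPORT <- function(k = 4L) {
  bases <- c("A", "C", "G", "T")
  sort(apply(do.call(expand.grid,
                     rep(list(bases), k))[, k:1, drop = FALSE],
             1, paste, collapse = ""))
}

#' Extract 5'-oriented end motifs of fragments
#'
#' The 5' motif is the reference sequence at the first k bases of the
#' fragment; the 3' motif is the reverse complement of the last k bases, so
#' both are reported 5'->3' as the true sequences at the fragment overhang
#' ends. Motifs overlapping an N, and fragments out of genome bounds, are
#' returned as NA.
#'
#' @param fragments a GRanges (1-based inclusive).
#' @param genome a [Biostrings::DNAStringSet] with names matching the
#'   fragment seqnames.
#' @param k motif length (default 4).
#' @return data.frame with columns motif5, motif3 (character, NA where
#'   skipped).
#' @export
fragmentEndMotifs <- function(fragments, genome, k = 4L) {
  n <- length(fragments)
  m5 <- rep(NA_character_, n)
  m3 <- rep(NA_character_, n)
  if (n == 0L) return(data.frame(motif5 = m5, motif3 = m3))
  chroms <- as.character(GenomicRanges::seqnames(fragments))
  starts <- GenomicRanges::start(fragments)
  ends <- GenomicRanges::end(fragments)
  widths <- GenomicRanges::width(fragments)
  tooShort <- widths < k
  for (chr in unique(chroms)) {
    if (!chr %in% names(genome)) {
      warning("fragments on unknown sequence '", chr, "' skipped")
      next
    }
    seq1 <- genome[[chr]]
    L <- length(seq1)
    idx <- which(chroms == chr & !tooShort)
    inb5 <- idx[starts[idx] >= 1L & starts[idx] + k - 1L <= L]
    inb3 <- idx[ends[idx] - k + 1L >= 1L & ends[idx] <= L]
    if (length(inb5) < length(idx) || length(inb3) < length(idx))
      warning("out-of-bounds fragment end(s) on '", chr, "' skipped")
    if (length(inb5)) {
      v5 <- Biostrings::extractAt(
        seq1, IRanges::IRanges(start = starts[inb5], width = k))
      m5[inb5] <- as.character(v5)
    }
    if (length(inb3)) {
      v3 <- Biostrings::extractAt(
        seq1, IRanges::IRanges(end = ends[inb3], width = k))
      m3[inb3] <- as.character(Biostrings::reverseComplement(v3))
    }
  }
  hasN <- function(x) !is.na(x) & grepl("[^ACGT]", x)
  m5[hasN(m5)] <- NA_character_
  m3[hasN(m3)] <- NA_character_
  data.frame(motif5 = m5, motif3 = m3, stringsAsFactors = FALSE)
}

#' Observed end-motif frequencies for one sample
#'
#' Both end motifs of every fragment are pooled into a single frequency
#' table over the 256 possible 4-mers; skipped motifs (N-containing or out
#' of bounds) are counted but excluded from the support.
#'
#' @param fragments a GRanges.
#' @param genome a DNAStringSet.
#' @param k motif length.
#' @param perEnd if TRUE, also return separate 5'/3' frequency vectors.
#' @return list with `freq` (named numeric over all 4^k motifs, summing to
#'   1), `counted`, `skipped`, and optionally `freq5`/`freq3`.
#' @export
motifFrequencies <- function(fragments, genome, k = 4L, perEnd = FALSE) {
  em <- fragmentEndMotifs(fragments, genome, k)
  pool <- c(em$motif5, em$motif3)
  counted <- sum(!is.na(pool))
  if (counted == 0L) stop("no countable end motifs")
  support <- .MOTIF_SUPPORT(k)
  tab <- table(factor(pool[!is.na(pool)], levels = support))
  out <- list(freq = as.numeric(tab) / counted,
              counted = counted, skipped = sum(is.na(pool)))
  names(out$freq) <- support
  if (perEnd) {
    f <- function(x) {
      t1 <- table(factor(x[!is.na(x)], levels = support))
      stats::setNames(as.numeric(t1) / max(1L, sum(t1)), support)
    }
    out$freq5 <- f(em$motif5)
    out$freq3 <- f(em$motif3)
  }
  out
}

#' Expected k-mer frequencies of a genome
#'
#' Exact sliding-window k-mer counts over both strands (forward sequence
#' plus its reverse complement) by default, since fragment ends sample both
#' strands. Windows containing N are excluded; frequencies are normalised
#' to sum 1.
#'
#' @param genome a DNAStringSet.
#' @param k k-mer length.
#' @param bothStrands count the reverse complement too (default TRUE).
#' @return named numeric over all 4^k motifs summing to 1.
#' @export
expectedMotifFrequencies <- function(genome, k = 4L, bothStrands = TRUE) {
  if (min(Biostrings::width(genome)) < k)
    stop("genome sequences shorter than k")
  counts <- colSums(Biostrings::oligonucleotideFrequency(genome, width = k))
  if (bothStrands) {
    rc <- Biostrings::reverseComplement(genome)
    counts <- counts + colSums(
      Biostrings::oligonucleotideFrequency(rc, width = k))
  }
  counts[.MOTIF_SUPPORT(k)] / sum(counts)
}

#' Assemble a motif-by-sample frequency table
#'
#' @param fragmentsList named list of GRanges, one per sample.
#' @param genome a DNAStringSet.
#' @param k motif length.
#' @return numeric matrix samples x motifs (rows sum to 1).
#' @export
motifFrequencyTable <- function(fragmentsList, genome, k = 4L) {
  rows <- lapply(fragmentsList, function(fr)
    motifFrequencies(fr, genome, k)$freq)
  do.call(rbind, rows)
}

#' Differential end-motif usage between two groups
#'
#' Per motif: log2 fold change of group mean frequencies (with a
#' pseudo-frequency of half the smallest nonzero frequency in the table to
#' guard the log), two-sided Wilcoxon rank-sum p, and Benjamini-Hochberg q
#' over all tested motifs.
#'
#' @param freqTable samples x motifs matrix from [motifFrequencyTable()].
#' @param groups two-level factor over samples; fold changes are
#'   level1/level2.
#' @return data.frame: motif, lfc, p, q.
#' @export
differentialMotifUsage <- function(freqTable, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  i1 <- groups == levels(groups)[1]
  nz <- freqTable[freqTable > 0]
  pseudo <- if (length(nz)) min(nz) / 2 else .Machine$double.eps
  res <- apply(freqTable, 2, function(v) {
    m1 <- mean(v[i1]); m2 <- mean(v[!i1])
    p <- if (all(v == v[1])) 1 else
      suppressWarnings(stats::wilcox.test(v[i1], v[!i1])$p.value)
    c(lfc = log2((m1 + pseudo) / (m2 + pseudo)), p = p)
  })
  out <- data.frame(motif = colnames(freqTable),
                    lfc = res["lfc", ], p = res["p", ])
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Correlate end-motif frequencies with a covariate
#'
#' Pearson correlation per motif, samples with missing covariate dropped
#' pairwise, BH correction across motifs.
#'
#' @param freqTable samples x motifs matrix.
#' @param covariate numeric per sample (NA allowed).
#' @return data.frame: motif, r, p, q.
#' @export
motifCovariateCorrelation <- function(freqTable, covariate) {
  ok <- !is.na(covariate)
  if (sum(ok) < 3L) stop("need >= 3 paired observations")
  if (stats::sd(covariate[ok]) == 0) stop("zero-variance covariate")
  res <- apply(freqTable[ok, , drop = FALSE], 2, function(v) {
    if (stats::sd(v) == 0) return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(v, covariate[ok], method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(motif = colnames(freqTable),
                    r = res["r", ], p = res["p", ])
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
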
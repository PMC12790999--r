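# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by direct enumeration, not by calling package internals.

library(GenomicRanges)  # attach for interactive use; calls are qualified

# O(F x P) windowed-protection-score counter: literal application of the
# spanning / interior-endpoint rules at every position.
bruteWps <- function(s, e, tss, window = 120L, flank = 300L) {
  h <- window %/% 2L
  positions <- (tss - flank):(tss + flank - 1L)
  vapply(positions, function(p) {
    Ws <- p - h; We <- p + window - h
    span <- sum(s <= Ws & e >= We)
    interior <- sum((s > Ws & s < We) | (e > Ws & e < We))
    span - interior
  }, numeric(1))
}

# GRanges (1-based) from 0-based half-open fragment coordinates.
grFrom0 <- function(chrom, s, e) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = s + 1L, end = e))
}

# Exhaustive sliding-window k-mer tally on a character sequence; windows
# containing non-ACGT letters are skipped.
bruteKmerCounts <- function(seqChar, k = 4L) {
  support <- sort(apply(do.call(expand.grid,
                                rep(list(c("A", "C", "G", "T")), k))[,
                                  k:1, drop = FALSE],
                        1, paste, collapse = ""))
  counts <- setNames(integer(length(support)), support)
  L <- nchar(seqChar)
  for (i in seq_len(L - k + 1L)) {
    w <- substr(seqChar, i, i + k - 1L)
    if (w %in% support) counts[w] <- counts[w] + 1L
  }
  counts
}

revcompChar <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1)))
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins.
bruteFisherP <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_; n <- b + d; kk <- a + b
  aVals <- max(0, kk - n):min(kk, m)
  probs <- dhyper(aVals, m, n, kk)
  pObs <- dhyper(a, m, n, kk)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Fine grid search over the 2-simplex for two-column mixtures.
gridSearchMix2 <- function(sampleVec, col1, col2, step = 0.001) {
  ps <- seq(0, 1, by = step)
  sse <- vapply(ps, function(p)
    sum((sampleVec - (p * col1 + (1 - p) * col2))^2), numeric(1))
  ps[which.min(sse)]
}
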
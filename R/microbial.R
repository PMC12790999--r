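# Microbial cfDNA: genus abundances, outlier filter, differential
# abundance and culture concordance.

#' Build a genus abundance table from read counts
#'
#' Abundance = read count / total non-human reads of the sample. Entries
#' with fewer than `minReads` reads are treated as non-detections (NA);
#' the denominator is the sample's total non-human reads and is never
#' recomputed after filtering.
#'
#' @param counts integer matrix, genera x samples.
#' @param totals numeric; total non-human reads per sample (named or in
#'   column order).
#' @param minReads detection threshold (default 10).
#' @return a [TaxonTable-class].
#' @export
abundanceTable <- function(counts, totals, minReads = 10L) {
  counts <- as.matrix(counts)
  if (any(totals <= 0)) stop("totals must be positive")
  if (!is.null(names(totals)) && !is.null(colnames(counts)))
    totals <- totals[colnames(counts)]
  if (length(totals) != ncol(counts))
    stop("one total per sample required")
  ab <- sweep(counts, 2, totals, `/`)
  ab[counts < minReads] <- NA_real_
  new("TaxonTable", counts = counts, totals = as.numeric(totals),
      abundance = ab, minReads = as.integer(minReads))
}

#' Outlier filter on pooled genus abundances
#'
#' Pools every detected (sample, genus) abundance in the cohort, computes
#' its mean and SD, and flags entries at least `k` SDs above the mean
#' (default k = 3.5). Non-detections are excluded from the pooled
#' distribution. With `logScale = TRUE` the rule is applied to log10
#' abundances.
#'
#' @param table a [TaxonTable-class].
#' @param k SD multiplier.
#' @param logScale apply the rule on log10 abundances.
#' @return list with `flags` (data.frame sample, genus, abundance),
#'   `threshold` (abundance-scale cutoff), `mean` and `sd` of the pooled
#'   distribution.
#' @export
outlierFilter <- function(table, k = 3.5, logScale = FALSE) {
  ab <- taxonAbundance(table)
  vals <- ab[!is.na(ab)]
  if (length(vals) < 3L) stop("need >= 3 detected abundances")
  x <- if (logScale) log10(vals) else vals
  mu <- mean(x); sdev <- stats::sd(x)
  empty <- data.frame(sample = character(), genus = character(),
                      abundance = numeric())
  if (sdev == 0)
    return(list(flags = empty, threshold = Inf, mean = mu, sd = sdev))
  thr <- mu + k * sdev
  thrAb <- if (logScale) 10^thr else thr
  idx <- which(!is.na(ab) & (if (logScale) log10(ab) else ab) >= thr,
               arr.ind = TRUE)
  flags <- if (nrow(idx)) data.frame(
    sample = colnames(ab)[idx[, 2]],
    genus = rownames(ab)[idx[, 1]],
    abundance = ab[idx]) else empty
  list(flags = flags[order(-flags$abundance), , drop = FALSE],
       threshold = thrAb, mean = mu, sd = sdev)
}

#' Differential genus abundance between two groups
#'
#' Per genus: two-sided Wilcoxon rank-sum test on abundances (genera not
#' detected in a sample count as abundance 0 -- absence is informative),
#' log2 fold change of group means with a pseudo-abundance of half the
#' smallest detected abundance, and BH correction across genera.
#'
#' @param table a [TaxonTable-class].
#' @param groups two-level factor per sample; fold changes are
#'   level1/level2.
#' @return data.frame: genus, lfc, p, q.
#' @export
differentialAbundance <- function(table, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  ab <- taxonAbundance(table)
  ab[is.na(ab)] <- 0
  i1 <- groups == levels(groups)[1]
  nz <- ab[ab > 0]
  pseudo <- if (length(nz)) min(nz) / 2 else .Machine$double.eps
  res <- apply(ab, 1, function(v) {
    p <- if (all(v == v[1])) 1 else
      suppressWarnings(stats::wilcox.test(v[i1], v[!i1])$p.value)
    c(lfc = log2((mean(v[i1]) + pseudo) / (mean(v[!i1]) + pseudo)), p = p)
  })
  out <- data.frame(genus = rownames(ab), lfc = res["lfc", ],
                    p = res["p", ])
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Concordance of flagged microbial signals with culture results
#'
#' Builds the 2x2 table (flagged vs background) x (culture-confirmed vs
#' not) and applies a two-sided Fisher exact test. The odds ratio is the
#' sample odds ratio, Haldane-corrected (+0.5 per cell) when any cell is
#' zero.
#'
#' @param flagged data.frame with columns sample, genus (the outlier
#'   calls).
#' @param background data.frame with columns sample, genus (detected,
#'   non-flagged signals; must be disjoint from `flagged`).
#' @param cultureConfirmed named logical per genus (TRUE = seen in blood
#'   or bodily-fluid culture for that patient cohort).
#' @return list with `table` (2x2), `proportions` (confirmed fraction in
#'   each arm), `oddsRatio`, `p`.
#' @export
cultureConcordance <- function(flagged, background, cultureConfirmed) {
  key <- function(df) paste(df$sample, df$genus)
  if (length(intersect(key(flagged), key(background))))
    stop("flagged and background sets must be disjoint")
  conf <- function(df) {
    v <- cultureConfirmed[df$genus]
    v[is.na(v)] <- FALSE
    sum(v)
  }
  a <- conf(flagged); b <- nrow(flagged) - a
  c_ <- conf(background); d <- nrow(background) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("flagged", "background"),
                                c("confirmed", "not_confirmed")))
  if (any(rowSums(tab) == 0) || all(tab[, 1] == 0) && all(tab[, 2] == 0))
    stop("empty margin in the 2x2 table")
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (any(tab == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  else (a * d) / (b * c_)
  list(table = tab,
       proportions = c(flagged = if (nrow(flagged)) a / nrow(flagged)
                       else NA_real_,
                       background = if (nrow(background))
                         c_ / nrow(background) else NA_real_),
       oddsRatio = or, p = p)
}

#' Flatten a Kraken2 report to genus-level counts
#'
#' Keeps rows with rank code "G" and returns the clade read counts, the
#' usual input for genus-level abundance analysis.
#'
#' @param path a Kraken2 report file (6 tab-separated columns: percent,
#'   clade reads, direct reads, rank code, taxid, name).
#' @return data.frame with columns genus, reads.
#' @export
flattenKrakenReport <- function(path) {
  df <- utils::read.delim(path, header = FALSE, strip.white = FALSE,
                          col.names = c("pct", "clade_reads", "reads",
                                        "rank", "taxid", "name"))
  g <- df[df$rank == "G", , drop = FALSE]
  data.frame(genus = trimws(g$name), reads = g$clade_reads,
             stringsAsFactors = FALSE)
}
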
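# Fragment I/O, length distributions, size classes, fragmentation index.

#' Read cfDNA fragments from a BED3 or TSV file
#'
#' BED3 is 0-based half-open; coordinates are converted to the 1-based
#' inclusive convention of GRanges. Malformed records (fewer than three
#' fields, non-numeric coordinates, end <= start) are rejected and reported
#' with their line numbers; a TSV header line is detected and skipped.
#'
#' @param path file path.
#' @param format "bed3" or "tsv" (both tab-delimited chrom/start/end; tsv
#'   may carry a header and extra columns).
#' @return a [GenomicRanges::GRanges]; rejected line numbers are attached
#'   as attribute "rejected".
#' @export
readFragments <- function(path, format = c("bed3", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    warning("empty fragment file: ", path)
    gr <- GenomicRanges::GRanges()
    attr(gr, "rejected") <- integer()
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lineno <- seq_along(lines)
  if (format == "tsv" && length(fields) > 0) {
    f1 <- fields[[1]]
    if (length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[2])))) {
      fields <- fields[-1]; lineno <- lineno[-1] # header
    }
  }
  n <- length(fields)
  chrom <- character(n); s <- rep(NA_real_, n); e <- rep(NA_real_, n)
  nf <- lengths(fields) >= 3L
  chrom[nf] <- vapply(fields[nf], `[`, character(1), 1L)
  s[nf] <- suppressWarnings(as.numeric(vapply(fields[nf], `[`,
                                              character(1), 2L)))
  e[nf] <- suppressWarnings(as.numeric(vapply(fields[nf], `[`,
                                              character(1), 3L)))
  bad <- !nf | is.na(s) | is.na(e) | e <= s | s < 0
  if (any(bad))
    warning(sum(bad), " malformed record(s) rejected at line(s): ",
            paste(utils::head(lineno[bad], 20), collapse = ", "),
            if (sum(bad) > 20) " ..." else "")
  keep <- !bad
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[keep],
    ranges = IRanges::IRanges(start = as.integer(s[keep]) + 1L,
                              end = as.integer(e[keep])))
  attr(gr, "rejected") <- lineno[bad]
  gr
}

#' Write fragments as BED3
#'
#' @param fragments a GRanges.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFragmentsBed <- function(fragments, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(fragments)),
                   start = GenomicRanges::start(fragments) - 1L,
                   end = GenomicRanges::end(fragments))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tabulate fragment lengths
#'
#' @param fragments a GRanges (or integer vector of lengths).
#' @return data.frame with columns `length` and `count`, sorted by length;
#'   total count equals the number of fragments.
#' @export
lengthHistogram <- function(fragments) {
  lens <- if (is.numeric(fragments)) as.integer(fragments)
          else GenomicRanges::width(fragments)
  if (length(lens) == 0L)
    return(data.frame(length = integer(), count = integer()))
  tab <- table(lens)
  data.frame(length = as.integer(names(tab)),
             count = as.integer(tab))
}

#' Classify fragment lengths into nucleosomal size classes
#'
#' Boundaries follow the operational definition: subnucleosomal < 120 bp,
#' mononucleosomal 120-250 bp, dinucleosomal 251-420 bp, polynucleosomal
#' > 420 bp (all inclusive at the stated edges).
#'
#' @param hist a length histogram from [lengthHistogram()].
#' @param bounds named numeric: `subMax` (exclusive upper bound of sub),
#'   `monoMax`, `diMax` (inclusive upper bounds of mono/di).
#' @return list with `proportions` (named numeric over the four classes,
#'   summing to 1) and `modal` (per-class modal length, NA where a class is
#'   empty).
#' @export
classifySizes <- function(hist,
                          bounds = c(subMax = 120, monoMax = 250,
                                     diMax = 420)) {
  total <- sum(hist$count)
  if (total == 0L) stop("cannot classify an empty histogram")
  cls <- cut(hist$length,
             breaks = c(-Inf, bounds[["subMax"]] - 0.5,
                        bounds[["monoMax"]] + 0.5,
                        bounds[["diMax"]] + 0.5, Inf),
             labels = c("subnucleosomal", "mononucleosomal",
                        "dinucleosomal", "polynucleosomal"))
  counts <- vapply(levels(cls), function(l)
    sum(hist$count[cls == l]), numeric(1))
  modal <- vapply(levels(cls), function(l) {
    h <- hist[cls == l, , drop = FALSE]
    if (nrow(h) == 0) NA_real_ else h$length[which.max(h$count)]
  }, numeric(1))
  list(proportions = counts / total, modal = modal)
}

#' Fragmentation index (mononucleosome : dinucleosome peak ratio)
#'
#' FI = count(length == 167) / count(length == 334) on raw counts at the
#' exact modal lengths. With `peakMode = TRUE` the numerator and
#' denominator are instead the maxima of the histogram within the mono
#' (120-250) and di (251-420) ranges.
#'
#' @param hist a length histogram from [lengthHistogram()].
#' @param monoLength,diLength exact lengths used (defaults 167 and 334).
#' @param peakMode use within-class peak counts instead of exact lengths.
#' @return list with `value` (NA when undefined), `numerator`,
#'   `denominator`, and `defined` (FALSE when the denominator count is 0).
#' @export
fragmentationIndex <- function(hist, monoLength = 167L, diLength = 334L,
                               peakMode = FALSE) {
  countAt <- function(len) {
    i <- match(len, hist$length)
    if (is.na(i)) 0L else hist$count[i]
  }
  if (peakMode) {
    monoH <- hist[hist$length >= 120 & hist$length <= 250, , drop = FALSE]
    diH <- hist[hist$length >= 251 & hist$length <= 420, , drop = FALSE]
    num <- if (nrow(monoH)) max(monoH$count) else 0L
    den <- if (nrow(diH)) max(diH$count) else 0L
  } else {
    num <- countAt(monoLength)
    den <- countAt(diLength)
  }
  list(value = if (den > 0) num / den else NA_real_,
       numerator = num, denominator = den, defined = den > 0)
}

#' Compare a per-sample statistic between two groups
#'
#' Reports both the Welch t-test and the Wilcoxon rank-sum test (two
#' sided); the caller selects whichever suits the distribution.
#'
#' @param values numeric per sample.
#' @param groups factor/character of group labels (exactly two levels).
#' @return data.frame with one row per test: statistic, p.value.
#' @export
compareGroups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  if (isTRUE(all.equal(c(g1, g2), rep(c(g1, g2)[1], length(values))))) {
    # fully degenerate data: no evidence of a difference
    return(data.frame(test = c("welch_t", "wilcoxon"),
                      statistic = c(0, length(g1) * length(g2) / 2),
                      p.value = c(1, 1)))
  }
  tt <- stats::t.test(g1, g2)
  wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = TRUE))
  data.frame(test = c("welch_t", "wilcoxon"),
             statistic = c(unname(tt$statistic), unname(wt$statistic)),
             p.value = c(tt$p.value, wt$p.value))
}
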
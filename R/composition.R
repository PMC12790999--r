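# Hierarchical methylome deconvolution and cellular-turnover estimation.

#' Create a reference atlas from a matrix or TSV file
#'
#' @param x numeric matrix (regions x cell types, rownames/colnames set)
#'   or path to a TSV whose first column holds region ids.
#' @return a [ReferenceAtlas-class].
#' @export
referenceAtlas <- function(x) {
  if (is.character(x)) {
    df <- utils::read.delim(x, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    x <- m
  }
  new("ReferenceAtlas", values = x)
}

#' Merge a tissue atlas with an immune-cell atlas
#'
#' Appends one "immune cells" column to the tissue atlas, defined as the
#' weighted average of the immune atlas columns with each cell type
#' weighted by its average proportion in whole blood (weights are
#' normalised to sum 1). Region support is intersected and the number of
#' dropped regions reported.
#'
#' @param tissueAtlas,immuneAtlas [ReferenceAtlas-class] objects.
#' @param wholeBloodWeights named numeric >= 0 over (a subset of) the
#'   immune atlas cell types; at least one positive.
#' @param immuneLabel name of the appended column.
#' @return the merged [ReferenceAtlas-class].
#' @export
mergeReferences <- function(tissueAtlas, immuneAtlas, wholeBloodWeights,
                            immuneLabel = "immune cells") {
  common <- intersect(atlasRegions(tissueAtlas), atlasRegions(immuneAtlas))
  if (length(common) == 0L) stop("no shared regions between atlases")
  dropped <- length(atlasRegions(tissueAtlas)) - length(common)
  if (dropped > 0)
    message(dropped, " tissue-atlas region(s) without immune-atlas ",
            "support dropped")
  w <- wholeBloodWeights[names(wholeBloodWeights) %in%
                           atlasCellTypes(immuneAtlas)]
  if (length(w) == 0L || any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with at least one positive entry ",
         "matching an immune cell type")
  w <- w / sum(w)
  imm <- atlasValues(immuneAtlas)[common, names(w), drop = FALSE]
  merged <- cbind(atlasValues(tissueAtlas)[common, , drop = FALSE],
                  as.numeric(imm %*% w))
  colnames(merged)[ncol(merged)] <- immuneLabel
  new("ReferenceAtlas", values = merged)
}

# Huber-weighted nonnegative least squares with a free intercept:
# centering sample and atlas columns solves min over p >= 0, c free of
# ||y - Xp - c||^2, so uniform off-reference background is absorbed by
# the intercept instead of distorting the coefficients. Optional
# iterative reweighting shrinks the influence of outlying regions.
.nnlsRobust <- function(A, b, robust = FALSE, huberK = 1.345,
                        maxIter = 25L, intercept = TRUE) {
  if (intercept) {
    A <- sweep(A, 2, colMeans(A))
    b <- b - mean(b)
  }
  beta <- pracma::lsqnonneg(A, b)$x
  if (robust) {
    for (it in seq_len(maxIter)) {
      r <- b - as.numeric(A %*% beta)
      s <- stats::mad(r)
      if (s <= .Machine$double.eps) break
      u <- abs(r) / (huberK * s)
      w <- ifelse(u <= 1, 1, 1 / u)
      betaNew <- pracma::lsqnonneg(A * sqrt(w), b * sqrt(w))$x
      if (max(abs(betaNew - beta)) < 1e-10) { beta <- betaNew; break }
      beta <- betaNew
    }
  }
  beta
}

#' Deconvolve one methylation sample against a reference atlas
#'
#' Nonnegative least squares (optionally Huber-reweighted for robustness
#' to outlying regions) of the sample methylation vector on the atlas
#' columns, followed by renormalisation onto the simplex. Regions missing
#' in the sample are dropped pairwise; a near-rank-deficient atlas is
#' flagged via the attached condition number.
#'
#' The regression carries a free intercept (as in robust
#' partial-correlation estimators), so methylation signal uniform across
#' the reference regions -- e.g. from cell types absent from the atlas --
#' is absorbed rather than forced into the coefficients.
#'
#' @param sample named numeric of methylation proportions per region.
#' @param atlas a [ReferenceAtlas-class].
#' @param robust use Huber reweighting (default FALSE).
#' @param intercept include the free intercept (default TRUE).
#' @param condLimit condition-number threshold above which the estimate is
#'   flagged.
#' @return named numeric of cell-type proportions summing to 1, with
#'   attributes `condition` (atlas condition number) and `flagged`.
#' @export
deconvolve <- function(sample, atlas, robust = FALSE, intercept = TRUE,
                       condLimit = 1e8) {
  common <- intersect(names(sample)[!is.na(sample)], atlasRegions(atlas))
  if (length(common) < ncol(atlasValues(atlas)))
    stop("fewer usable regions than cell types")
  A <- atlasValues(atlas)[common, , drop = FALSE]
  b <- sample[common]
  cn <- kappa(A, exact = FALSE)
  beta <- .nnlsRobust(A, as.numeric(b), robust = robust,
                      intercept = intercept)
  tot <- sum(beta)
  p <- if (tot > 0) beta / tot else rep(1 / length(beta), length(beta))
  names(p) <- atlasCellTypes(atlas)
  attr(p, "condition") <- cn
  attr(p, "flagged") <- cn > condLimit || tot == 0
  p
}

#' Two-step hierarchical deconvolution
#'
#' Step 1 deconvolves the sample against the tissue atlas augmented with a
#' whole-blood-weighted "immune cells" column (see [mergeReferences()]);
#' step 2 splits the estimated immune fraction into immune cell types by a
#' second deconvolution against the immune atlas. Final proportions are
#' the solid-tissue proportions plus immune fraction times the step-2
#' proportions, and sum to 1.
#'
#' @param sample named numeric of methylation proportions per region.
#' @param tissueAtlas,immuneAtlas [ReferenceAtlas-class] objects.
#' @param wholeBloodWeights named numeric; see [mergeReferences()].
#' @param robust use Huber reweighting in both steps.
#' @return named numeric of final cell-type proportions (tissues then
#'   immune cell types), with attribute `immuneFraction`.
#' @export
hierarchicalDeconvolve <- function(sample, tissueAtlas, immuneAtlas,
                                   wholeBloodWeights, robust = FALSE) {
  immuneLabel <- "immune cells"
  merged <- mergeReferences(tissueAtlas, immuneAtlas, wholeBloodWeights,
                            immuneLabel = immuneLabel)
  step1 <- deconvolve(sample, merged, robust = robust)
  immuneFrac <- unname(step1[immuneLabel])
  tissueP <- step1[setdiff(names(step1), immuneLabel)]
  immuneTypes <- atlasCellTypes(immuneAtlas)
  if (immuneFrac > 0) {
    step2 <- deconvolve(sample, immuneAtlas, robust = robust)
    immuneP <- immuneFrac * step2
  } else {
    immuneP <- stats::setNames(rep(0, length(immuneTypes)), immuneTypes)
  }
  out <- c(tissueP, immuneP[immuneTypes])
  attr(out, "immuneFraction") <- immuneFrac
  out
}

#' Genome equivalents per ml of plasma
#'
#' GEQ/ml = p_i x purity x (yield / 0.006), where p_i is the cfDNA
#' proportion attributed to cell type i, purity the fraction of DNA that
#' is true cfDNA, yield the DNA recovered per ml plasma (ng/ml), and
#' 0.006 ng the DNA content of one diploid genome. GEQ/ml is proportional
#' to the number of cell deaths of that type.
#'
#' @param p cfDNA proportion for the cell type (vectorised).
#' @param purity cfDNA purity fraction in [0,1].
#' @param yield DNA yield, ng per ml plasma.
#' @param genomeMass ng of DNA per genome (default 0.006).
#' @return genomes per ml.
#' @export
geqPerMl <- function(p, purity, yield, genomeMass = 0.006) {
  if (any(p < 0) || any(purity < 0) || any(purity > 1) || any(yield < 0))
    stop("p and yield must be >= 0 and purity in [0,1]")
  p * purity * (yield / genomeMass)
}

#' Cellular turnover: GEQ/ml over circulating cells/ml
#'
#' A ratio of 1 marks equality between cell death (cfDNA genome
#' equivalents) and standing circulating cells of the type.
#'
#' @param geqPerMl genomes per ml (from [geqPerMl()]).
#' @param cellsPerMl circulating cells per ml from a complete blood count.
#' @return list with geq_per_ml, cells_per_ml and ratio.
#' @export
turnover <- function(geqPerMl, cellsPerMl) {
  if (any(cellsPerMl <= 0)) stop("cellsPerMl must be positive")
  list(geq_per_ml = geqPerMl, cells_per_ml = cellsPerMl,
       ratio = geqPerMl / cellsPerMl)
}
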
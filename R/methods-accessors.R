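# Accessors and show() methods for the core S4 containers.

#' @rdname WpsProfile-class
#' @export
setMethod("wpsDistance", "WpsProfile", function(x) x@distance)

#' @rdname WpsProfile-class
#' @export
setMethod("wpsRaw", "WpsProfile", function(x) x@raw)

#' @rdname WpsProfile-class
#' @export
setMethod("wpsAdjusted", "WpsProfile", function(x) x@adjusted)

#' @rdname WpsProfile-class
#' @export
setMethod("wpsSmoothed", "WpsProfile", function(x) x@smoothed)

#' @rdname WpsProfile-class
#' @export
setMethod("nGenes", "WpsProfile", function(x) x@nGenes)

#' @rdname WpsProfile-class
#' @export
setMethod("wpsCi", "WpsProfile", function(x)
  data.frame(distance = x@distance, low = x@ciLow, high = x@ciHigh))

setMethod("show", "WpsProfile", function(object) {
  cat("WpsProfile over", length(object@distance), "positions [",
      min(object@distance), ",", max(object@distance), "] bp;",
      object@nGenes, "gene(s)\n")
  if (!all(is.na(object@smoothed)))
    cat("  smoothed range:",
        sprintf("%.3f .. %.3f", min(object@smoothed), max(object@smoothed)),
        "\n")
})

#' @rdname OscillatorFit-class
#' @export
setMethod("oscParams", "OscillatorFit", function(x) x@params)

#' @rdname OscillatorFit-class
#' @export
setMethod("oscPeriod", "OscillatorFit", function(x)
  2 * pi / x@params[["omega"]])

#' @rdname OscillatorFit-class
#' @export
setMethod("isConverged", "OscillatorFit", function(x) x@converged)

#' @rdname OscillatorFit-class
#' @export
setMethod("fitRmse", "OscillatorFit", function(x) x@rmse)

setMethod("show", "OscillatorFit", function(object) {
  p <- object@params
  cat("OscillatorFit (", if (object@converged) "converged" else "NOT converged",
      ")\n", sep = "")
  cat(sprintf("  kappa=%.4g A=%.4g lambda=%.4g omega=%.4g phi=%.4g b=%.4g\n",
              p[["kappa"]], p[["A"]], p[["lambda"]], p[["omega"]],
              p[["phi"]], p[["b"]]))
  cat(sprintf("  period=%.1f bp, rmse=%.4g over %d points in [%g, %g]\n",
              2 * pi / p[["omega"]], object@rmse, object@nPoints,
              object@fitRegion[1], object@fitRegion[2]))
})

#' @rdname ReferenceAtlas-class
#' @export
setMethod("atlasValues", "ReferenceAtlas", function(x) x@values)

#' @rdname ReferenceAtlas-class
#' @export
setMethod("atlasRegions", "ReferenceAtlas", function(x) rownames(x@values))

#' @rdname ReferenceAtlas-class
#' @export
setMethod("atlasCellTypes", "ReferenceAtlas", function(x) colnames(x@values))

setMethod("show", "ReferenceAtlas", function(object) {
  cat("ReferenceAtlas:", nrow(object@values), "regions x",
      ncol(object@values), "cell types\n")
  cat("  cell types:", paste(utils::head(colnames(object@values), 6),
                             collapse = ", "),
      if (ncol(object@values) > 6) "..." else "", "\n")
})

#' @rdname TaxonTable-class
#' @export
setMethod("taxonCounts", "TaxonTable", function(x) x@counts)

#' @rdname TaxonTable-class
#' @export
setMethod("taxonAbundance", "TaxonTable", function(x) x@abundance)

#' @rdname TaxonTable-class
#' @export
setMethod("taxonTotals", "TaxonTable", function(x) x@totals)

setMethod("show", "TaxonTable", function(object) {
  cat("TaxonTable:", nrow(object@counts), "genera x", ncol(object@counts),
      "samples (detection filter: >=", object@minReads, "reads)\n")
  cat("  detected entries:", sum(!is.na(object@abundance)), "\n")
})
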
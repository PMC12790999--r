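#' @rdname WpsProfile-class
#' @param object,x a `WpsProfile`, `OscillatorFit`, `ReferenceAtlas` or
#'   `TaxonTable` object, as documented per accessor.
#' @export
setGeneric("wpsDistance", function(x) standardGeneric("wpsDistance"))

#' @rdname WpsProfile-class
#' @export
setGeneric("wpsRaw", function(x) standardGeneric("wpsRaw"))

#' @rdname WpsProfile-class
#' @export
setGeneric("wpsAdjusted", function(x) standardGeneric("wpsAdjusted"))

#' @rdname WpsProfile-class
#' @export
setGeneric("wpsSmoothed", function(x) standardGeneric("wpsSmoothed"))

#' @rdname WpsProfile-class
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname WpsProfile-class
#' @export
setGeneric("wpsCi", function(x) standardGeneric("wpsCi"))

#' @rdname OscillatorFit-class
#' @export
setGeneric("oscParams", function(x) standardGeneric("oscParams"))

#' @rdname OscillatorFit-class
#' @export
setGeneric("oscPeriod", function(x) standardGeneric("oscPeriod"))

#' @rdname OscillatorFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname OscillatorFit-class
#' @export
setGeneric("fitRmse", function(x) standardGeneric("fitRmse"))

#' @rdname ReferenceAtlas-class
#' @export
setGeneric("atlasValues", function(x) standardGeneric("atlasValues"))

#' @rdname ReferenceAtlas-class
#' @export
setGeneric("atlasRegions", function(x) standardGeneric("atlasRegions"))

#' @rdname ReferenceAtlas-class
#' @export
setGeneric("atlasCellTypes", function(x) standardGeneric("atlasCellTypes"))

#' @rdname TaxonTable-class
#' @export
setGeneric("taxonCounts", function(x) standardGeneric("taxonCounts"))

#' @rdname TaxonTable-class
#' @export
setGeneric("taxonAbundance", function(x) standardGeneric("taxonAbundance"))

#' @rdname TaxonTable-class
#' @export
setGeneric("taxonTotals", function(x) standardGeneric("taxonTotals"))
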
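#' @import methods
NULL

#' Simulation configuration for the synthetic cfDNA cohort generator
#'
#' Holds every tunable of the synthetic-data generator: genome composition,
#' gene/TSS layout, the phased nucleosome-array model downstream of active
#' TSSs, background fragment mixture, cleavage end-motif bias and noise.
#'
#' @slot seed integer; master seed, all generators derive from it.
#' @slot genomeLength integer; synthetic genome length in bp.
#' @slot gcContent numeric in [0,1]; expected GC fraction of the genome.
#' @slot nGenes integer; number of TSSs to place.
#' @slot activeFraction numeric in [0,1]; fraction of genes labelled active.
#' @slot nucleosomeRepeat integer bp; inter-nucleosome spacing of phased
#'   arrays (default 187, the canonical repeat length at active promoters).
#' @slot protectedLength integer bp; nucleosome-protected fragment length
#'   (default 167: core particle plus linker stubs).
#' @slot firstNucleosomeOffset integer bp; distance from the TSS to the +1
#'   nucleosome center (a nucleosome-free-region width surrogate).
#' @slot jitterBaseSd,jitterGrowthSd numeric bp; per-fragment positional
#'   jitter of nucleosome n has SD = jitterBaseSd + n * jitterGrowthSd, so
#'   phasing decays with nucleosome index.
#' @slot lengthSd numeric bp; SD of Gaussian noise on protected fragment
#'   lengths.
#' @slot fragmentsPerNucleosome integer; fragments sampled per nucleosome
#'   per active gene.
#' @slot backgroundRate numeric; background fragments per bp of genome.
#' @slot classMix named numeric over sub/mono/di/poly summing to 1; length
#'   mixture of background fragments (sub 50-119, mono 120-250, di 251-420,
#'   poly 421-700 bp, uniform within class).
#' @slot ccEndBias numeric >= 0; odds multiplier applied when resampling
#'   fragments whose reference 4-mer at the 5' start begins "CC" (1 = no
#'   bias).
#' @slot noiseSd numeric; Gaussian noise SD for directly simulated WPS
#'   profiles, in WPS units.
#' @seealso [simConfig()] for the user-facing constructor.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  genomeLength = "integer",
  gcContent = "numeric",
  nGenes = "integer",
  activeFraction = "numeric",
  nucleosomeRepeat = "integer",
  protectedLength = "integer",
  firstNucleosomeOffset = "integer",
  jitterBaseSd = "numeric",
  jitterGrowthSd = "numeric",
  lengthSd = "numeric",
  fragmentsPerNucleosome = "integer",
  backgroundRate = "numeric",
  classMix = "numeric",
  ccEndBias = "numeric",
  noiseSd = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@genomeLength < 1L) msg <- c(msg, "genomeLength must be positive")
  if (object@gcContent < 0 || object@gcContent > 1)
    msg <- c(msg, "gcContent must be in [0,1]")
  if (object@nGenes < 0L) msg <- c(msg, "nGenes must be >= 0")
  if (object@activeFraction < 0 || object@activeFraction > 1)
    msg <- c(msg, "activeFraction must be in [0,1]")
  if (abs(sum(object@classMix) - 1) > 1e-8)
    msg <- c(msg, "classMix must sum to 1")
  if (!setequal(names(object@classMix), c("sub", "mono", "di", "poly")))
    msg <- c(msg, "classMix must be named sub/mono/di/poly")
  if (any(object@classMix < 0)) msg <- c(msg, "classMix entries must be >= 0")
  if (object@ccEndBias < 0) msg <- c(msg, "ccEndBias must be >= 0")
  if (object@fragmentsPerNucleosome < 0L || object@backgroundRate < 0)
    msg <- c(msg, "fragment counts and rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Windowed protection score profile around a TSS
#'
#' Per-position protection scores on a transcription-oriented distance grid
#' (negative = upstream of the TSS). Raw scores are the spanning-minus-broken
#' fragment counts; adjusted scores are mean-centred over the span; smoothed
#' scores are the Gaussian-smoothed adjusted signal. Aggregated profiles
#' (nGenes > 1) carry a 95% confidence band across genes.
#'
#' @slot distance integer vector; signed distance from the TSS in bp.
#' @slot raw numeric; raw integer-valued WPS (NA for simulated/aggregated
#'   profiles that have no raw stage).
#' @slot adjusted numeric; mean-centred WPS.
#' @slot smoothed numeric; Gaussian-smoothed adjusted WPS.
#' @slot nGenes integer; number of genes averaged (1 for a single region).
#' @slot ciLow,ciHigh numeric; 95% confidence band across genes (NA unless
#'   aggregated).
#' @export
setClass("WpsProfile", representation(
  distance = "integer",
  raw = "numeric",
  adjusted = "numeric",
  smoothed = "numeric",
  nGenes = "integer",
  ciLow = "numeric",
  ciHigh = "numeric"
))

setValidity("WpsProfile", function(object) {
  n <- length(object@distance)
  lens <- c(length(object@raw), length(object@adjusted),
            length(object@smoothed), length(object@ciLow),
            length(object@ciHigh))
  if (any(lens != n))
    return("all score tracks must have the same length as the distance grid")
  if (is.unsorted(object@distance, strictly = TRUE))
    return("distance grid must be strictly increasing")
  TRUE
})

#' Two-stage damped harmonic oscillator fit of a WPS profile
#'
#' The phasing model WPS(d) = exp(-kappa d) + A exp(-lambda d) cos(omega d -
#' phi) + b, fitted over a fixed distance window by non-linear least squares
#' in two stages (exponential trend first, oscillator on its residuals).
#'
#' @slot params named numeric with elements kappa, A, lambda, omega, phi, b.
#' @slot converged logical; FALSE when either NLS stage failed.
#' @slot rmse numeric; root-mean-square error of the full model on the fit
#'   region.
#' @slot stage1Rmse numeric; RMSE of the stage-1 exponential trend alone.
#' @slot fitRegion numeric length 2; distance window used, bp from the TSS.
#' @slot nPoints integer; number of fitted observations.
#' @seealso [fitTwoStage()], [oscPeriod()]
#' @export
setClass("OscillatorFit", representation(
  params = "numeric",
  converged = "logical",
  rmse = "numeric",
  stage1Rmse = "numeric",
  fitRegion = "numeric",
  nPoints = "integer"
))

setValidity("OscillatorFit", function(object) {
  need <- c("kappa", "A", "lambda", "omega", "phi", "b")
  if (!all(need %in% names(object@params)))
    return("params must contain kappa, A, lambda, omega, phi, b")
  if (length(object@fitRegion) != 2L)
    return("fitRegion must have length 2")
  TRUE
})

#' Region-by-cell-type methylation reference atlas
#'
#' A matrix of methylation proportions (rows = marker regions, columns =
#' cell types), the reference for mixture deconvolution.
#'
#' @slot values numeric matrix in [0,1] with unique rownames (region ids)
#'   and colnames (cell types).
#' @export
setClass("ReferenceAtlas", representation(values = "matrix"))

setValidity("ReferenceAtlas", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("atlas matrix needs region rownames and cell-type colnames")
  if (anyDuplicated(rownames(v))) return("duplicate region ids")
  ok <- is.na(v) | (v >= 0 & v <= 1)
  if (!all(ok)) return("methylation values must lie in [0,1]")
  TRUE
})

#' Per-sample genus read counts and abundances
#'
#' Genus-level read counts per sample together with total non-human read
#' counts. Abundance of a genus is its read count divided by the sample's
#' total non-human reads; entries below the minimum-read detection filter
#' are recorded as NA (non-detections, not zeros) and the denominator is
#' never recomputed after filtering.
#'
#' @slot counts integer matrix, genera x samples.
#' @slot totals named numeric; total non-human reads per sample.
#' @slot abundance numeric matrix, genera x samples; counts/totals with
#'   entries failing the detection filter set NA.
#' @slot minReads integer; per-(sample, genus) detection threshold.
#' @export
setClass("TaxonTable", representation(
  counts = "matrix",
  totals = "numeric",
  abundance = "matrix",
  minReads = "integer"
))

setValidity("TaxonTable", function(object) {
  if (!identical(dim(object@counts), dim(object@abundance)))
    return("counts and abundance must have identical dimensions")
  if (ncol(object@counts) != length(object@totals))
    return("one total per sample required")
  if (any(object@totals <= 0)) return("totals must be positive")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})
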
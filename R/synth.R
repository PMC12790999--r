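# Synthetic-data generators. Every generator is a pure function of
# (config, seed): internal seeds are derived from config@seed with fixed
# per-generator offsets so the same config always yields the same cohort.

#' Build a simulation configuration
#'
#' Defaults describe a realistic cfDNA sample: a 1-Mb genome at 41% GC,
#' phased nucleosome arrays with a 187-bp repeat downstream of active TSSs,
#' 167-bp protected fragments, positional jitter growing with nucleosome
#' index (so phasing decays with distance from the TSS), and a background
#' length mixture dominated by mononucleosomal fragments (90.8% mono, 5.2%
#' di, 0.6% poly, remainder subnucleosomal).
#'
#' @param seed integer master seed.
#' @param genomeLength genome length in bp.
#' @param gcContent expected GC fraction.
#' @param nGenes number of TSSs to place.
#' @param activeFraction fraction of genes labelled active.
#' @param nucleosomeRepeat inter-nucleosome spacing, bp.
#' @param protectedLength nucleosome-protected fragment length, bp.
#' @param firstNucleosomeOffset TSS to +1 nucleosome center distance, bp.
#' @param jitterBaseSd,jitterGrowthSd positional jitter SD of nucleosome n
#'   is jitterBaseSd + n * jitterGrowthSd, bp.
#' @param lengthSd SD of fragment-length noise, bp.
#' @param fragmentsPerNucleosome fragments per nucleosome per active gene.
#' @param backgroundRate background fragments per bp.
#' @param classMix named proportions over sub/mono/di/poly.
#' @param ccEndBias odds multiplier for fragments whose reference 4-mer at
#'   the 5' start begins "CC" (1 disables the bias).
#' @param noiseSd Gaussian noise SD for directly simulated WPS profiles.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 7, genomeLength = 5e4L, nGenes = 5L)
#' @export
simConfig <- function(seed = 1L,
                      genomeLength = 1e6L,
                      gcContent = 0.41,
                      nGenes = 100L,
                      activeFraction = 0.5,
                      nucleosomeRepeat = 187L,
                      protectedLength = 167L,
                      firstNucleosomeOffset = 100L,
                      jitterBaseSd = 5,
                      jitterGrowthSd = 2,
                      lengthSd = 5,
                      fragmentsPerNucleosome = 50L,
                      backgroundRate = 0.005,
                      classMix = c(sub = 0.034, mono = 0.908,
                                   di = 0.052, poly = 0.006),
                      ccEndBias = 1,
                      noiseSd = 0.05) {
  new("SimConfig",
      seed = as.integer(seed),
      genomeLength = as.integer(genomeLength),
      gcContent = gcContent,
      nGenes = as.integer(nGenes),
      activeFraction = activeFraction,
      nucleosomeRepeat = as.integer(nucleosomeRepeat),
      protectedLength = as.integer(protectedLength),
      firstNucleosomeOffset = as.integer(firstNucleosomeOffset),
      jitterBaseSd = jitterBaseSd,
      jitterGrowthSd = jitterGrowthSd,
      lengthSd = lengthSd,
      fragmentsPerNucleosome = as.integer(fragmentsPerNucleosome),
      backgroundRate = backgroundRate,
      classMix = classMix[c("sub", "mono", "di", "poly")],
      ccEndBias = ccEndBias,
      noiseSd = noiseSd)
}

# background fragment length bounds per size class
.CLASS_BOUNDS <- list(sub = c(50L, 119L), mono = c(120L, 250L),
                      di = c(251L, 420L), poly = c(421L, 700L))

#' Generate a synthetic genome sequence
#'
#' i.i.d. bases at the configured GC content, as a single chromosome named
#' "chrS".
#'
#' @param config a [SimConfig-class].
#' @return a [Biostrings::DNAStringSet] of length 1.
#' @export
generateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  if (config@genomeLength < 1L) stop("genome length must be positive")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config@seed)
  gc <- config@gcContent
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), config@genomeLength, replace = TRUE, prob = p)
  gn <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(gn) <- "chrS"
  gn
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a TSS annotation table
#'
#' Places `nGenes` TSSs on the genome with at least 6 kb between any two
#' (so 5-kb TSS windows never overlap) and at least 2.5 kb of flank inside
#' the genome on both sides. Strand is ~50/50 and an activity label is
#' drawn with probability `activeFraction`.
#'
#' @param config a [SimConfig-class].
#' @param genome the genome from [generateGenome()] (used for bounds).
#' @return data.frame with columns gene_id, chrom, tss (0-based bp),
#'   strand, activity.
#' @export
generateGenes <- function(config, genome) {
  stopifnot(is(config, "SimConfig"))
  L <- Biostrings::width(genome)[1]
  n <- config@nGenes
  if (n == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      tss = integer(), strand = character(),
                      activity = character(), stringsAsFactors = FALSE))
  margin <- 3000L # >= 2.5 kb flank with headroom
  slot <- (L - 2L * margin) %/% n
  if (slot < 6000L)
    stop("genome too short for ", n, " genes with 6-kb spacing")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config@seed + 1L)
  jitter <- floor(stats::runif(n, 0, slot - 6000L + 1))
  tss <- margin + (seq_len(n) - 1L) * slot + as.integer(jitter)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  activity <- ifelse(stats::runif(n) < config@activeFraction,
                     "active", "inactive")
  data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
             chrom = names(genome)[1], tss = tss, strand = strand,
             activity = activity, stringsAsFactors = FALSE)
}

#' Simulate cfDNA fragments over a synthetic genome
#'
#' Active genes receive ten phased nucleosomes, the n-th centred at
#' TSS + firstNucleosomeOffset + n * nucleosomeRepeat in the direction of
#' transcription, each fragment's centre perturbed with Gaussian jitter of
#' SD jitterBaseSd + n * jitterGrowthSd so that phasing decays with
#' distance from the TSS. Background fragments fall uniformly over the
#' genome with lengths drawn from the configured size-class mixture;
#' inactive genes see background only. With `ccEndBias != 1` the fragment
#' set is importance-resampled so fragments whose reference 4-mer at the
#' fragment start begins "CC" get their sampling odds multiplied by the
#' bias, emulating nuclease cleavage preference.
#'
#' @param config a [SimConfig-class].
#' @param genes TSS table from [generateGenes()].
#' @param genome genome from [generateGenome()].
#' @return a [GenomicRanges::GRanges] of fragments (1-based, inclusive).
#' @export
simulateFragments <- function(config, genes, genome) {
  stopifnot(is(config, "SimConfig"))
  L <- Biostrings::width(genome)[1]
  chrom <- names(genome)[1]
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config@seed + 2L)

  starts <- integer(0); lens <- integer(0)
  active <- genes[genes$activity == "active", , drop = FALSE]
  nNuc <- 10L
  if (nrow(active) > 0 && config@fragmentsPerNucleosome > 0L) {
    for (n in 0:(nNuc - 1L)) {
      dir <- ifelse(active$strand == "+", 1L, -1L)
      center0 <- active$tss + dir *
        (config@firstNucleosomeOffset + n * config@nucleosomeRepeat)
      m <- config@fragmentsPerNucleosome
      cent <- rep(center0, each = m) +
        stats::rnorm(nrow(active) * m,
                     sd = config@jitterBaseSd + n * config@jitterGrowthSd)
      len <- pmax(30L, as.integer(round(
        config@protectedLength +
          stats::rnorm(nrow(active) * m, sd = config@lengthSd))))
      s <- as.integer(round(cent - len / 2))
      starts <- c(starts, s); lens <- c(lens, len)
    }
  }
  nBg <- as.integer(round(config@backgroundRate * L))
  if (nBg > 0L) {
    cls <- sample(names(config@classMix), nBg, replace = TRUE,
                  prob = config@classMix)
    lo <- vapply(.CLASS_BOUNDS[cls], `[`, integer(1), 1L)
    hi <- vapply(.CLASS_BOUNDS[cls], `[`, integer(1), 2L)
    len <- lo + as.integer(floor(stats::runif(nBg) * (hi - lo + 1L)))
    s <- as.integer(floor(stats::runif(nBg) * pmax(1L, L - len)))
    starts <- c(starts, s); lens <- c(lens, len)
  }
  if (length(starts) == 0L)
    return(GenomicRanges::GRanges(seqnames = character(),
                                  ranges = IRanges::IRanges()))
  # clip to genome
  starts <- pmax(0L, pmin(starts, L - lens))
  ends <- starts + lens # 0-based half-open

  if (config@ccEndBias != 1) {
    seq1 <- genome[[1]]
    k <- 4L
    okIdx <- starts + k <= L
    first2 <- rep(NA_character_, length(starts))
    v <- Biostrings::extractAt(
      seq1, IRanges::IRanges(start = starts[okIdx] + 1L, width = 2L))
    first2[okIdx] <- as.character(v)
    w <- ifelse(!is.na(first2) & first2 == "CC", config@ccEndBias, 1)
    keep <- sample(seq_along(starts), length(starts), replace = TRUE,
                   prob = w)
    starts <- starts[keep]; ends <- ends[keep]
  }
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts + 1L, end = ends))
}

#' Simulate a WPS profile directly from the oscillator model
#'
#' Evaluates WPS(d) = exp(-kappa d) + A exp(-lambda d) cos(omega d - phi)
#' + b on a distance grid and adds i.i.d. Gaussian noise.
#'
#' @param params named numeric with kappa, A, lambda, omega, phi, b (see
#'   [oscillatorParams()]).
#' @param grid integer distance grid, bp from the TSS.
#' @param noiseSd Gaussian noise SD in WPS units (0 gives exact model
#'   values).
#' @param seed integer seed for the noise.
#' @return a [WpsProfile-class] whose adjusted and smoothed tracks hold the
#'   simulated values.
#' @export
simulateWpsDirect <- function(params, grid = -2500:2499, noiseSd = 0,
                              seed = 1L) {
  grid <- as.integer(grid)
  mu <- modelPredict(params, grid)
  if (noiseSd > 0) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
    mu <- mu + stats::rnorm(length(grid), sd = noiseSd)
  }
  new("WpsProfile", distance = grid, raw = rep(NA_real_, length(grid)),
      adjusted = mu, smoothed = mu, nGenes = 1L,
      ciLow = rep(NA_real_, length(grid)),
      ciHigh = rep(NA_real_, length(grid)))
}

#' Build a synthetic methylation reference atlas
#'
#' Each cell type receives `nMarkers` private hypomethylated marker regions
#' (value `markerValue`) on a hypermethylated background (`background`),
#' the hypo/hyper marker structure that makes reference-based deconvolution
#' identifiable.
#'
#' @param cellTypes character vector of cell-type names.
#' @param nRegions total number of regions (must be >= length(cellTypes) *
#'   nMarkers).
#' @param nMarkers private markers per cell type.
#' @param background,markerValue methylation levels of background and
#'   marker regions.
#' @param noiseSd optional Gaussian jitter on atlas values (clipped to
#'   [0,1]).
#' @param seed integer seed.
#' @return a [ReferenceAtlas-class].
#' @export
simulateAtlas <- function(cellTypes, nRegions = 200L, nMarkers = 20L,
                          background = 0.85, markerValue = 0.05,
                          noiseSd = 0, seed = 1L) {
  k <- length(cellTypes)
  if (nRegions < k * nMarkers)
    stop("need at least ", k * nMarkers, " regions")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  v <- matrix(background, nrow = nRegions, ncol = k,
              dimnames = list(sprintf("region%04d", seq_len(nRegions)),
                              cellTypes))
  for (i in seq_len(k)) {
    rows <- ((i - 1L) * nMarkers + 1L):(i * nMarkers)
    v[rows, i] <- markerValue
  }
  if (noiseSd > 0)
    v <- pmin(1, pmax(0, v + stats::rnorm(length(v), sd = noiseSd)))
  new("ReferenceAtlas", values = v)
}

#' Simulate a methylation sample from a known cell-type mixture
#'
#' Region value = sum over cell types of proportion x atlas value, plus
#' truncated Gaussian noise (clipped to [0,1]).
#'
#' @param atlas a [ReferenceAtlas-class].
#' @param trueProportions named numeric on the simplex over the atlas cell
#'   types (tolerance 1e-6).
#' @param noiseSd Gaussian noise SD on methylation proportions.
#' @param seed integer seed.
#' @return named numeric vector of methylation proportions per region.
#' @export
simulateMethylation <- function(atlas, trueProportions, noiseSd = 0,
                                seed = 1L) {
  stopifnot(is(atlas, "ReferenceAtlas"))
  p <- trueProportions[atlasCellTypes(atlas)]
  if (anyNA(p) || any(p < -1e-6) || abs(sum(p) - 1) > 1e-6)
    stop("trueProportions must lie on the simplex over the atlas cell types")
  mu <- as.numeric(atlasValues(atlas) %*% p)
  if (noiseSd > 0) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
    mu <- mu + stats::rnorm(length(mu), sd = noiseSd)
  }
  mu <- pmin(1, pmax(0, mu))
  names(mu) <- atlasRegions(atlas)
  mu
}

#' Simulate genus read-count tables with contaminant background
#'
#' Each sample's non-human reads are multinomial over a contaminant genus
#' profile; planted pathogen signals take the requested share of a sample's
#' total reads, with the remainder going to contaminants.
#'
#' @param nSamples number of samples.
#' @param contaminantProfile named numeric; relative contaminant genus
#'   abundances (normalised internally).
#' @param planted data.frame with columns sample (index), genus, abundance
#'   in (0,1); may be NULL.
#' @param totalReads total non-human reads per sample (scalar or vector).
#' @param seed integer seed.
#' @return list with `counts` (genus x sample integer matrix) and `totals`
#'   (named numeric of non-human reads per sample).
#' @export
simulateTaxa <- function(nSamples, contaminantProfile, planted = NULL,
                         totalReads = 1e5, seed = 1L) {
  prof <- contaminantProfile / sum(contaminantProfile)
  totals <- rep_len(totalReads, nSamples)
  if (!is.null(planted) && nrow(planted) > 0 &&
      any(planted$abundance <= 0 | planted$abundance >= 1))
    stop("planted abundances must lie in (0,1)")
  genera <- union(names(prof), if (is.null(planted)) character()
                  else planted$genus)
  counts <- matrix(0L, nrow = length(genera), ncol = nSamples,
                   dimnames = list(genera, sprintf("S%02d",
                                                   seq_len(nSamples))))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  for (j in seq_len(nSamples)) {
    tot <- totals[j]
    nPlant <- 0L
    if (!is.null(planted)) {
      pj <- planted[planted$sample == j, , drop = FALSE]
      if (nrow(pj) > 0) {
        reads <- as.integer(round(pj$abundance * tot))
        counts[pj$genus, j] <- counts[pj$genus, j] + reads
        nPlant <- sum(reads)
      }
    }
    bg <- stats::rmultinom(1, size = tot - nPlant, prob = prof)[, 1]
    counts[names(prof), j] <- counts[names(prof), j] + as.integer(bg)
  }
  list(counts = counts, totals = stats::setNames(totals, colnames(counts)))
}
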
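# Synthetic-data generators: determinism, composition, spacing, mixtures.

test_that("genome generation is seed-deterministic and hits target GC", {
  cfg <- simConfig(seed = 11, genomeLength = 2e4L)
  g1 <- generateGenome(cfg)
  g2 <- generateGenome(cfg)
  expect_identical(as.character(g1), as.character(g2))

  gcOnly <- generateGenome(simConfig(seed = 3, genomeLength = 1e4L,
                                     gcContent = 1))
  expect_false(grepl("[AT]", as.character(gcOnly[[1]])))

  big <- generateGenome(simConfig(seed = 5, genomeLength = 1e6L,
                                  gcContent = 0.5))
  gc <- sum(Biostrings::alphabetFrequency(big[[1]])[c("C", "G")]) / 1e6
  expect_gt(gc, 0.48)  # binomial concentration at n = 1e6
  expect_lt(gc, 0.52)
})

test_that("gene placement respects flanks and pairwise 6-kb spacing", {
  cfg <- simConfig(seed = 2, genomeLength = 3e5L, nGenes = 30L)
  genome <- generateGenome(cfg)
  genes <- generateGenes(cfg, genome)
  expect_equal(nrow(genes), 30L)
  expect_true(all(genes$tss >= 2500 &
                    genes$tss <= cfg@genomeLength - 2500))
  d <- abs(outer(genes$tss, genes$tss, `-`))
  expect_true(all(d[upper.tri(d)] >= 6000))  # exhaustive pairwise check

  empty <- generateGenes(simConfig(seed = 2, genomeLength = 3e5L,
                                   nGenes = 0L), genome)
  expect_equal(nrow(empty), 0L)
  shortCfg <- simConfig(seed = 1, genomeLength = 5e4L, nGenes = 30L)
  expect_error(generateGenes(shortCfg, generateGenome(shortCfg)),
               "too short")
})

test_that("fragment simulation honours mixtures, jitter growth and bias", {
  cfg0 <- simConfig(seed = 4, genomeLength = 5e4L, nGenes = 3L,
                    fragmentsPerNucleosome = 0L, backgroundRate = 0)
  genome <- generateGenome(cfg0)
  genes <- generateGenes(cfg0, genome)
  expect_length(simulateFragments(cfg0, genes, genome), 0L)

  cfgMono <- simConfig(seed = 4, genomeLength = 2e5L, nGenes = 0L,
                       backgroundRate = 0.05,
                       classMix = c(sub = 0, mono = 1, di = 0, poly = 0))
  gMono <- generateGenome(cfgMono)
  frM <- simulateFragments(cfgMono,
                           generateGenes(cfgMono, gMono), gMono)
  expect_gt(length(frM), 1e3)
  expect_true(all(GenomicRanges::width(frM) >= 120 &
                    GenomicRanges::width(frM) <= 250))

  # jitter SD grows with nucleosome index: one active plus-strand gene
  cfgJ <- simConfig(seed = 9, genomeLength = 5e4L, nGenes = 1L,
                    activeFraction = 1, fragmentsPerNucleosome = 1500L,
                    backgroundRate = 0, jitterBaseSd = 3,
                    jitterGrowthSd = 3, lengthSd = 0)
  gJ <- generateGenome(cfgJ)
  genesJ <- generateGenes(cfgJ, gJ)
  frJ <- simulateFragments(cfgJ, genesJ, gJ)
  centers <- (GenomicRanges::start(frJ) - 1 +
                GenomicRanges::end(frJ)) / 2
  dirSign <- if (genesJ$strand == "+") 1 else -1
  expected <- genesJ$tss + dirSign * (100 + (0:9) * cfgJ@nucleosomeRepeat)
  nucIdx <- apply(abs(outer(centers, expected, `-`)), 1, which.min)
  sds <- tapply(centers, nucIdx, sd)
  expect_true(all(diff(sds) > 0))  # monotone at 1500 fragments/nucleosome
})

test_that("CC end bias enriches CC-starting 5' motifs over baseline", {
  cfg <- simConfig(seed = 21, genomeLength = 1e5L, nGenes = 0L,
                   backgroundRate = 0.1, ccEndBias = 4)
  genome <- generateGenome(cfg)
  genes <- generateGenes(cfg, genome)
  fr <- simulateFragments(cfg, genes, genome)
  obs <- motifFrequencies(fr, genome)$freq
  expected <- expectedMotifFrequencies(genome)
  ccIdx <- startsWith(names(obs), "CC")
  expect_gt(sum(obs[ccIdx]), sum(expected[ccIdx]))
})

test_that("direct WPS simulation matches the model and noise level", {
  p <- oscillatorParams(kappa = 0, A = 0, lambda = 0, omega = 2 * pi / 187,
                        phi = 0, b = 0)
  flat <- simulateWpsDirect(p, -100:100, noiseSd = 0)
  expect_equal(wpsSmoothed(flat), rep(1, 201))  # model reduces to e^0

  p2 <- oscillatorParams(0.002, 0.5, 0.001, 2 * pi / 187, 0.3, 0.1)
  prof <- simulateWpsDirect(p2, -185:925, noiseSd = 0)
  expect_equal(wpsSmoothed(prof), modelPredict(p2, -185:925))

  noisy <- simulateWpsDirect(p2, -500:999, noiseSd = 0.05, seed = 8)
  resid <- wpsSmoothed(noisy) - modelPredict(p2, -500:999)
  expect_gt(sd(resid), 0.045)  # chi-square bound at n = 1500
  expect_lt(sd(resid), 0.055)

  again <- simulateWpsDirect(p2, -500:999, noiseSd = 0.05, seed = 8)
  expect_identical(wpsSmoothed(noisy), wpsSmoothed(again))
})

test_that("methylation mixtures combine atlas columns exactly", {
  atlas <- simulateAtlas(c("ct1", "ct2", "ct3"), nRegions = 120L,
                         seed = 5)
  pure <- simulateMethylation(atlas, c(ct1 = 1, ct2 = 0, ct3 = 0))
  expect_equal(unname(pure), unname(atlasValues(atlas)[, "ct1"]))

  half <- simulateMethylation(atlas, c(ct1 = 0.5, ct2 = 0.5, ct3 = 0))
  expect_equal(unname(half),
               unname((atlasValues(atlas)[, "ct1"] +
                         atlasValues(atlas)[, "ct2"]) / 2))

  noisy <- simulateMethylation(atlas, c(ct1 = 0.3, ct2 = 0.3, ct3 = 0.4),
                               noiseSd = 0.3, seed = 2)
  expect_true(all(noisy >= 0 & noisy <= 1))
  expect_error(simulateMethylation(atlas, c(ct1 = 0.9, ct2 = 0.9,
                                            ct3 = 0)),
               "simplex")
})

test_that("taxa simulation respects totals and planted abundances", {
  prof <- setNames(rep(1 / 10, 10), paste0("g", 1:10))
  sim <- simulateTaxa(4, prof, totalReads = 2e4, seed = 3)
  expect_equal(unname(colSums(sim$counts)), rep(2e4, 4))

  planted <- data.frame(sample = 2, genus = "Pathogen", abundance = 0.4)
  sim2 <- simulateTaxa(6, prof, planted, totalReads = 5e4, seed = 3)
  expect_equal(unname(colSums(sim2$counts)), rep(5e4, 6))
  expect_equal(sim2$counts["Pathogen", 2] / 5e4, 0.4, tolerance = 1e-6)
  expect_error(simulateTaxa(3, prof,
                            data.frame(sample = 1, genus = "x",
                                       abundance = 1.2)),
               "abundances")
})
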
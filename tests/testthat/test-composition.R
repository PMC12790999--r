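# Reference merging, deconvolution, genome equivalents, turnover.

mkAtlas <- function(m) new("ReferenceAtlas", values = m)

test_that("reference merging builds the weighted immune column", {
  regions <- c("r1", "r2")
  tissue <- mkAtlas(matrix(c(0.9, 0.1), ncol = 1,
                           dimnames = list(regions, "hepatocyte")))
  immune <- mkAtlas(matrix(c(0.2, 0.8, 0.6, 0.4), ncol = 2,
                           dimnames = list(regions,
                                           c("neutrophil", "monocyte"))))
  merged <- mergeReferences(tissue, immune,
                            c(neutrophil = 0.75, monocyte = 0.25))
  expect_equal(unname(atlasValues(merged)[, "immune cells"]),
               c(0.3, 0.7))  # hand-computed weighted average

  one <- mergeReferences(tissue, immune, c(neutrophil = 1))
  expect_equal(unname(atlasValues(one)[, "immune cells"]), c(0.2, 0.8))

  twin <- mkAtlas(matrix(c(0.2, 0.8, 0.2, 0.8), ncol = 2,
                         dimnames = list(regions, c("a", "b"))))
  mTwin <- mergeReferences(tissue, twin, c(a = 0.3, b = 0.7))
  expect_equal(unname(atlasValues(mTwin)[, "immune cells"]), c(0.2, 0.8))

  expect_error(mergeReferences(tissue, immune,
                               c(neutrophil = 0, monocyte = 0)),
               "positive")
})

test_that("deconvolution recovers pure columns and 50/50 mixtures", {
  atlas <- simulateAtlas(paste0("ct", 1:5), nRegions = 200L, seed = 1)
  pure <- simulateMethylation(atlas,
                              setNames(c(1, 0, 0, 0, 0),
                                       paste0("ct", 1:5)))
  p <- deconvolve(pure, atlas)
  expect_equal(unname(p["ct1"]), 1, tolerance = 1e-6)

  half <- simulateMethylation(atlas,
                              setNames(c(0.5, 0.5, 0, 0, 0),
                                       paste0("ct", 1:5)))
  pH <- deconvolve(half, atlas)
  # two-column grid-search oracle over the simplex
  oracle <- gridSearchMix2(half, atlasValues(atlas)[, "ct1"],
                           atlasValues(atlas)[, "ct2"])
  expect_lt(abs(pH[["ct1"]] - 0.5), 0.02)
  expect_lt(abs(pH[["ct1"]] - oracle), 0.02)
})

test_that("deconvolution stays within 0.05 MAE under noise and its error
           grows with the noise level", {
  atlas <- simulateAtlas(paste0("ct", 1:5), nRegions = 200L, seed = 2)
  truth <- setNames(c(0.4, 0.25, 0.2, 0.1, 0.05), paste0("ct", 1:5))
  maes <- vapply(1:20, function(seed) {
    s <- simulateMethylation(atlas, truth, noiseSd = 0.05, seed = seed)
    mean(abs(deconvolve(s, atlas) - truth))
  }, numeric(1))
  expect_lte(mean(maes), 0.05)

  sdGrid <- c(0, 0.05, 0.15, 0.3)
  err <- vapply(sdGrid, function(sdv) {
    mean(vapply(1:8, function(seed) {
      s <- simulateMethylation(atlas, truth, noiseSd = sdv, seed = seed)
      mean(abs(deconvolve(s, atlas) - truth))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) > 0))  # monotone in noise SD
})

test_that("hierarchical deconvolution splits the immune fraction and
           sums to one", {
  # one consistent world: tissue and immune references are column subsets
  # of a single master atlas over shared regions
  tissues <- c("hepatocyte", "neuron")
  immune <- c("neutrophil", "monocyte", "lymphocyte")
  master <- simulateAtlas(c(tissues, immune), nRegions = 200L, seed = 3)
  tissueAtlas <- referenceAtlas(atlasValues(master)[, tissues])
  immuneAtlas <- referenceAtlas(atlasValues(master)[, immune])
  w <- c(neutrophil = 0.6, monocyte = 0.4)

  pureHep <- simulateMethylation(master,
                                 c(hepatocyte = 1, neuron = 0,
                                   neutrophil = 0, monocyte = 0,
                                   lymphocyte = 0))
  pH <- hierarchicalDeconvolve(pureHep, tissueAtlas, immuneAtlas, w)
  expect_equal(unname(pH["hepatocyte"]), 1, tolerance = 0.02)
  expect_true(all(pH[immune] < 0.02))

  # synthetic truth: hepatocyte .5, neutrophil .3, monocyte .2
  truth <- c(hepatocyte = 0.5, neuron = 0, neutrophil = 0.3,
             monocyte = 0.2, lymphocyte = 0)
  mixedVec <- simulateMethylation(master, truth)
  est <- hierarchicalDeconvolve(mixedVec, tissueAtlas, immuneAtlas, w)
  expect_lt(abs(est[["hepatocyte"]] - 0.5), 0.05)
  expect_lt(abs(est[["neutrophil"]] - 0.3), 0.05)
  expect_lt(abs(est[["monocyte"]] - 0.2), 0.05)
  expect_equal(sum(est), 1, tolerance = 1e-6)

  set.seed(9)
  for (i in 1:5) {
    pr <- runif(2); pr <- pr / sum(pr) * 0.6
    v <- simulateMethylation(master,
                             c(hepatocyte = 1 - sum(pr), neuron = 0,
                               neutrophil = pr[1], monocyte = pr[2],
                               lymphocyte = 0))
    e <- hierarchicalDeconvolve(v, tissueAtlas, immuneAtlas, w)
    expect_equal(sum(e), 1, tolerance = 1e-6)
  }

  # hierarchical and flat deconvolution agree when the immune-column
  # weights equal the sample's true immune composition
  flat <- deconvolve(mixedVec, master)
  hier <- est[names(flat)]
  expect_true(all(abs(hier - flat) < 0.05))
})

test_that("genome equivalents and turnover follow their closed forms", {
  expect_equal(geqPerMl(1, 1, 0.006), 1)  # unit case: one genome per ml
  expect_equal(geqPerMl(0, 1, 10), 0)
  expect_equal(geqPerMl(0.372, 0.9, 10), 0.372 * 0.9 * 10 / 0.006)
  expect_equal(geqPerMl(0.372, 0.9, 10), 558)

  # separately linear in each argument
  expect_equal(geqPerMl(0.2 * 3, 0.5, 4), 3 * geqPerMl(0.2, 0.5, 4))
  expect_equal(geqPerMl(0.2, 0.5, 4 * 7), 7 * geqPerMl(0.2, 0.5, 4))

  expect_equal(turnover(4.5e6, 4.5e6)$ratio, 1)  # reference line
  expect_equal(turnover(0, 1e6)$ratio, 0)
  expect_equal(turnover(558, 4.5e6)$ratio, 558 / 4.5e6)
  expect_error(turnover(100, 0), "positive")
  expect_error(geqPerMl(-0.1, 1, 1), ">= 0")
})
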
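# Genus abundances, outlier filter, differential abundance, culture
# concordance.

test_that("abundance table applies the 10-read filter without
           recomputing denominators", {
  counts <- matrix(c(9L, 50L, 941L,
                     12L, 0L, 988L), ncol = 2,
                   dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  tab <- abundanceTable(counts, c(s1 = 1000, s2 = 1000))
  ab <- taxonAbundance(tab)
  expect_true(is.na(ab["gA", "s1"]))          # 9 reads: non-detection
  expect_equal(ab["gB", "s1"], 0.05)          # 50 / 1000
  expect_equal(ab["gA", "s2"], 0.012)
  expect_true(all(ab[!is.na(ab)] <= 1))
  expect_true(all(colSums(ab, na.rm = TRUE) <= 1))
  expect_error(abundanceTable(counts, c(s1 = 0, s2 = 1000)), "positive")
})

test_that("outlier filter thresholds at the pooled mean plus k SD", {
  eq <- matrix(rep(100L, 12), ncol = 3,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  tabEq <- abundanceTable(eq, rep(1000, 3))
  expect_equal(nrow(outlierFilter(tabEq)$flags), 0L)  # zero variance

  # 99 values at 0.001 and one at 0.5
  counts <- matrix(10L, nrow = 10, ncol = 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:10)))
  counts[1, 1] <- 5000L
  tab <- abundanceTable(counts, rep(1e4, 10))
  of <- outlierFilter(tab)
  vals <- c(rep(0.001, 99), 0.5)
  expect_lt(mean(vals) + 3.5 * sd(vals), 0.5)  # threshold sits below 0.5
  expect_equal(nrow(of$flags), 1L)
  expect_equal(of$flags$genus, "g1")
  expect_equal(of$flags$sample, "s1")
  expect_equal(of$threshold, mean(vals) + 3.5 * sd(vals))

  # anti-monotone in k; invariant to row/column order
  expect_lte(nrow(outlierFilter(tab, k = 5)$flags), nrow(of$flags))
  perm <- counts[sample(10), sample(10)]
  tabP <- abundanceTable(perm, rep(1e4, 10))
  ofP <- outlierFilter(tabP)
  expect_equal(ofP$threshold, of$threshold)
  expect_equal(ofP$flags$genus, of$flags$genus)
})

test_that("differential abundance finds planted signals and is
           calibrated under permutation", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    counts <- matrix(rpois(20 * 20, 40), nrow = 20,
                     dimnames = list(paste0("g", 1:20),
                                     paste0("s", 1:20)))
    counts[1, 1:10] <- rpois(10, 400)  # 10x in group 1
    tab <- abundanceTable(counts, rep(1e4, 20))
    res <- differentialAbundance(tab, rep(c("case", "ctrl"), each = 10))
    if (res$q[res$genus == "g1"] <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 16L)  # power >= 80% over 20 seeds

  pvals <- c()
  for (seed in 1:30) {
    set.seed(seed + 100)
    counts <- matrix(rpois(20 * 20, 40), nrow = 20,
                     dimnames = list(paste0("g", 1:20),
                                     paste0("s", 1:20)))
    tab <- abundanceTable(counts, rep(1e4, 20))
    res <- differentialAbundance(tab,
                                 sample(rep(c("a", "b"), each = 10)))
    pvals <- c(pvals, res$p)
  }
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 0.04)

  ident <- matrix(rep(c(100L, 200L), 4), nrow = 2, byrow = FALSE,
                  dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  resI <- differentialAbundance(abundanceTable(ident, rep(1e3, 4)),
                                c("a", "a", "b", "b"))
  expect_true(all(resI$lfc == 0))
})

test_that("culture concordance matches hypergeometric enumeration", {
  flagged <- data.frame(sample = paste0("s", 1:11),
                        genus = c(rep("Escherichia", 2),
                                  "Staphylococcus",
                                  rep("Enterococcus", 2),
                                  paste0("Other", 1:6)))
  background <- data.frame(sample = paste0("b", 1:171),
                           genus = c("Escherichia",
                                     paste0("Contam", 1:170)))
  confirmed <- c(Escherichia = TRUE, Staphylococcus = TRUE,
                 Enterococcus = FALSE)
  cc <- cultureConcordance(flagged, background, confirmed)
  expect_equal(unname(cc$table["flagged", "confirmed"]), 3)
  expect_equal(cc$p, bruteFisherP(cc$table))

  # transposition leaves the two-sided p unchanged
  expect_equal(fisher.test(t(cc$table))$p.value, cc$p)

  # no confirmed events anywhere: p = 1
  none <- cultureConcordance(
    data.frame(sample = "s1", genus = "X"),
    data.frame(sample = "s2", genus = "Y"),
    c(X = FALSE, Y = FALSE))
  expect_equal(none$p, 1)
  expect_error(cultureConcordance(flagged, flagged, confirmed),
               "disjoint")
})

test_that("a planted pathogen passes the whole microbial pipeline", {
  prof <- setNames(rep(1 / 30, 30), paste0("Contam", 1:30))
  planted <- data.frame(sample = 1:6, genus = "Klebsiella",
                        abundance = 0.4)
  sim <- simulateTaxa(12, prof, planted, totalReads = 5e4, seed = 77)
  tab <- abundanceTable(sim$counts, sim$totals)
  of <- outlierFilter(tab)
  expect_true(all(paste("Klebsiella", 1:6) %in%
                    paste(of$flags$genus,
                          match(of$flags$sample, colnames(sim$counts)))))
  groups <- rep(c("patient", "control"), c(6, 6))
  res <- differentialAbundance(tab, factor(groups,
                                           levels = c("patient",
                                                      "control")))
  expect_lte(res$q[res$genus == "Klebsiella"], 0.05)
  expect_gt(res$lfc[res$genus == "Klebsiella"], 0)
})

test_that("Kraken2 genus rows are flattened to counts", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    " 90.00\t9000\t0\tU\t0\tunclassified",
    "  5.00\t500\t10\tG\t561\t  Escherichia",
    "  4.00\t400\t400\tS\t562\t    Escherichia coli",
    "  1.00\t100\t100\tG\t570\t  Klebsiella"), path)
  df <- flattenKrakenReport(path)
  expect_equal(df$genus, c("Escherichia", "Klebsiella"))
  expect_equal(df$reads, c(500, 100))
})
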
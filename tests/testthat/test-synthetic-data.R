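# Synthetic-data generators: composition, determinism, and moment checks
# against closed-form oracles of the generative models.

test_that("library design has the requested composition", {
  d <- makeLibraryDesign(504, 10, 1000)
  g <- guideTable(d)
  expect_equal(sum(!g$is_ntc), 5040)
  expect_equal(length(libraryGenes(d)), 504)
  expect_equal(sum(g$is_ntc), 1000)
  expect_false(anyDuplicated(g$guide_id) > 0)

  empty <- makeLibraryDesign(0, 10, 5)
  expect_equal(sum(!guideTable(empty)$is_ntc), 0)
  expect_equal(sum(guideTable(empty)$is_ntc), 5)

  d1 <- makeLibraryDesign(3, 2, 1, list(P = "GENE0001"), seed = 7)
  d2 <- makeLibraryDesign(3, 2, 1, list(P = "GENE0001"), seed = 7)
  expect_equal(nrow(guideTable(d1)), 7)
  expect_identical(d1, d2)

  expect_error(makeLibraryDesign(-1, 10, 5), "non-negative")
})

test_that("screen simulator is reproducible and NTC ratios center on zero", {
  d <- smallDesign()
  s1 <- simulateScreen(d, seed = 42)
  s2 <- simulateScreen(d, seed = 42)
  expect_identical(assay(s1, "counts"), assay(s2, "counts"))

  lf <- guideLog2Ratios(normalizeCounts(simulateScreen(
    makeLibraryDesign(50, 4, 400), nReplicates = 3, seed = 9)))
  ntc <- lf$lfc[lf$is_ntc]
  sem <- sd(ntc) / sqrt(length(ntc))
  expect_lt(abs(mean(ntc)), 3 * sem)
})

test_that("a -0.25/doubling effect yields ~ -5 mean log2 ratio pre-renormalization", {
  # closed-form oracle: E log2(PD20/PD0) = effect * doublings = -5; checked
  # by averaging simulated guide ratios with depth renormalization off
  d <- makeLibraryDesign(1, 10, 50)
  eff <- data.frame(gene_id = "GENE0001", treatment = "TMZ", effect = -0.25)
  s <- simulateScreen(d, baselineMean = 2000, dispersion = 0.1,
                      geneEffects = eff, nReplicates = 50,
                      treatments = "TMZ", renormalizeDepth = FALSE,
                      seed = 11)
  cnt <- assay(s, "counts")
  cd <- as.data.frame(colData(s))
  i0 <- cd$timepoint == "PD0"; i20 <- cd$timepoint == "PD20"
  gene <- !rowData(s)$is_ntc
  ratios <- log2((cnt[gene, i20] + 0.5) / (cnt[gene, i0] + 0.5))
  expect_lt(abs(mean(ratios) - (-5)),
            max(3 * sd(ratios) / sqrt(length(ratios)), 0.05))
})

test_that("dispersion -> 0 approaches Poisson counts", {
  d <- makeLibraryDesign(0, 0, 10000)
  s0 <- simulateScreen(d, baselineMean = 100, dispersion = 0,
                       nReplicates = 1, treatments = "DMSO", seed = 3)
  x <- assay(s0, "counts")[, 1]
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)
  sod <- simulateScreen(d, baselineMean = 100, dispersion = 0.3,
                        nReplicates = 1, treatments = "DMSO", seed = 3)
  y <- assay(sod, "counts")[, 1]
  # NB oracle: var/mean = 1 + dispersion * mu = 31
  expect_gt(var(y) / mean(y), 20)
})

test_that("catalog simulator matches its Poisson/multinomial oracle", {
  sigs <- randomSignatures(3)
  arms <- data.frame(genotype = "WT", treatment = "TMZ", n_clones = 200L)
  sim <- simulateCatalogs(arms, sigs, c(400, 0, 0), seed = 5)
  totals <- totalSNV(sim$catalogs)
  expect_length(totals, 200)
  # Poisson SE oracle: SE(mean) = sqrt(400/200)
  expect_lt(abs(mean(totals) - 400), 3 * sqrt(400 / 200))

  zero <- simulateCatalogs(data.frame(genotype = "WT", treatment = "DMSO",
                                      n_clones = 4L),
                           sigs, c(0, 0, 0), seed = 5)
  expect_true(all(totalSNV(zero$catalogs) == 0))
  expect_equal(nrow(zero$variants), 0)

  arms2 <- data.frame(genotype = c("A", "B"), treatment = c("DMSO", "TMZ"),
                      n_clones = 6L)
  sim2 <- simulateCatalogs(arms2, sigs, c(50, 10, 0), seed = 6)
  cd <- as.data.frame(colData(sim2$catalogs))
  expect_equal(nrow(cd), 12)
  expect_equal(as.vector(table(cd$genotype)), c(6, 6))
  expect_error(simulateCatalogs(arms2, sigs, c(-1, 0, 0)), "non-negative")
})

test_that("summing per-variant records per clone reproduces the 96-vector", {
  sigs <- randomSignatures(2)
  sim <- simulateCatalogs(data.frame(genotype = "WT", treatment = "TMZ",
                                     n_clones = 5L),
                          sigs, c(120, 60), seed = 8)
  rebuilt <- buildCatalogs(sim$variants,
                           as.data.frame(colData(sim$catalogs)))
  expect_equal(assay(rebuilt, "contexts") + 0L,
               assay(sim$catalogs, "contexts") + 0L)
})

test_that("cohort generator obeys its logistic prevalence oracle", {
  co <- simulateCohort(4000, beta0 = -1, betaRad18 = 0, betaMgmt = 0,
                       seed = 10)
  p0 <- plogis(-1)
  expect_lt(abs(mean(co$hypermutation) - p0),
            3 * sqrt(p0 * (1 - p0) / 4000))
  # noiseSd -> 0 would be degenerate (disallowed); tiny noise ~ 0 residuals
  tiny <- simulateCohort(50, noiseSd = 1e-8, seed = 2)
  expect_lt(max(abs(adjustExpression(tiny)$rad18_adj)), 1e-6)
  expect_identical(simulateCohort(2000, seed = 3),
                   simulateCohort(2000, seed = 3))
  expect_error(simulateCohort(5), ">= 10")
})
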
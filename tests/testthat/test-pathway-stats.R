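# Gene Z contrasts, the combined pathway Z-test and the paired-t dropout
# statistic, checked against direct arithmetic and closed-form oracles.

test_that("gene Z contrast matches its arithmetic oracle", {
  z <- geneZstat(c(-2, -1, 0), c(1, 0, -1))
  expect_equal(z$x_g, -1)
  expect_equal(z$s_g, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(z$z_g, -1 / sqrt(2 / 3), tolerance = 1e-12)

  same <- geneZstat(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$x_g, 0)
  expect_equal(same$z_g, 0)

  # Z scales linearly in a mean shift at equal variances
  base <- geneZstat(c(0, 1, 2) + 1, c(0, 1, 2))
  shift <- geneZstat(c(0, 1, 2) + 2, c(0, 1, 2))
  expect_equal(shift$z_g, 2 * base$z_g, tolerance = 1e-12)

  expect_error(geneZstat(1, c(1, 2)), ">= 2")
  degen <- geneZstat(c(1, 1), c(1, 1))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$z_g))
})

test_that("pathway Z combines gene contrasts per the formula", {
  one <- data.frame(genotype = "WT", gene_id = "G1", x_g = -1,
                    s_g = sqrt(2 / 3))
  r1 <- pathwayZstat(one, list(G1 = "P"))
  expect_equal(r1$z_p, -1 / sqrt(2 / 3), tolerance = 1e-12)

  two <- data.frame(genotype = "WT", gene_id = c("G1", "G2"),
                    x_g = c(-1, -1), s_g = sqrt(c(2 / 3, 2 / 3)))
  r2 <- pathwayZstat(two, list(G1 = "P", G2 = "P"))
  expect_equal(r2$z_p, -2 / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(r2$p_value, 2 * pnorm(-sqrt(3)), tolerance = 1e-12)
  expect_equal(r2$n_genes, 2L)
})

test_that("pathway Z is invariant to gene order and additive partitioning", {
  withr::with_seed(13, {
    ctr <- data.frame(genotype = "WT",
                      gene_id = sprintf("G%02d", 1:20),
                      x_g = rnorm(20), s_g = runif(20, 0.2, 1))
  })
  pmap <- setNames(rep(list("P"), 20), ctr$gene_id)
  full <- pathwayZstat(ctr, pmap)
  shuf <- pathwayZstat(ctr[sample(20), ], pmap)
  expect_equal(shuf$z_p, full$z_p, tolerance = 1e-12)
  # merging subset sums gives the identical Z_P
  sub1 <- ctr[1:8, ]; sub2 <- ctr[9:20, ]
  zMerged <- (sum(sub1$x_g) + sum(sub2$x_g)) /
    sqrt(sum(sub1$s_g^2) + sum(sub2$s_g^2))
  expect_equal(full$z_p, zMerged, tolerance = 1e-12)
  # a gene with x = 0 and vanishing s changes nothing in the limit
  aug <- rbind(ctr, data.frame(genotype = "WT", gene_id = "G21",
                               x_g = 0, s_g = 1e-12))
  expect_equal(pathwayZstat(aug, c(pmap, list(G21 = "P")))$z_p, full$z_p,
               tolerance = 1e-6)
})

test_that("genes with zero variance are excluded with a warning", {
  ctr <- data.frame(genotype = "WT", gene_id = c("G1", "G2"),
                    x_g = c(-1, 5), s_g = c(0.5, 0))
  expect_warning(r <- pathwayZstat(ctr, list(G1 = "P", G2 = "P")),
                 "S_g = 0")
  expect_equal(r$n_genes, 1L)
  expect_equal(r$n_excluded, 1L)
  expect_error(suppressWarnings(
    pathwayZstat(data.frame(genotype = "WT", gene_id = "G2",
                            x_g = 5, s_g = 0), list(G2 = "P"))),
    "empty after exclusions")
})

test_that("paired-t matches the closed-form df=2 oracle and textbook t", {
  # differences (-1,-2,-3): t = -2*sqrt(3); df=2 CDF is 1/2 + t/(2 sqrt(2+t^2))
  d <- c(-1, -2, -3)
  tOracle <- mean(d) / (sd(d) / sqrt(3))
  pOracle <- 2 * (1 / 2 + tOracle / (2 * sqrt(2 + tOracle^2)))
  expect_equal(tOracle, -3.4641, tolerance = 1e-4)
  expect_equal(pOracle, 0.0742, tolerance = 1e-3)

  design <- makeLibraryDesign(1, 3, 0, pathwaySpec = list(P = "GENE0001"))
  mk <- function(p20) {
    cnt <- matrix(c(10, 100, 1000, p20), ncol = 2,
                  dimnames = list(guideTable(design)$guide_id,
                                  c("a", "b")))
    se <- ScreenExperiment(cnt, as.data.frame(guideTable(design)),
                           data.frame(sample = c("a", "b"),
                                      timepoint = c("PD0", "PD20"),
                                      treatment = "TMZ", genotype = "WT",
                                      replicate = 1))
    assays(se)$cpm <- cnt
    se
  }
  # log10 pairs then differ by exactly (-1, -2, -3) up to the pseudocount
  se <- mk(c(10, 100, 1000) * 10^c(-1, -2, -3))
  r <- pathwayPairedT(se, design, pseudocount = 1e-9)
  expect_equal(r$t_stat, -3.4641, tolerance = 1e-3)
  expect_equal(r$neg_log10_p, -log10(0.0742), tolerance = 1e-3)

  ident <- mk(c(10, 100, 1000))
  r0 <- pathwayPairedT(ident, design, pseudocount = 1e-9)
  expect_true(r0$degenerate)
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$neg_log10_p, 0)
  expect_equal(r0$log2_fc_pooled, 0)
})

test_that("paired-t agrees with textbook computation on random instances", {
  design <- makeLibraryDesign(1, 8, 0, pathwaySpec = list(P = "GENE0001"))
  gt <- guideTable(design)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    cnt <- withr::with_seed(100 + i,
      matrix(rpois(2 * n, 500) + 1, ncol = 2,
             dimnames = list(gt$guide_id[1:n], c("a", "b"))))
    se <- ScreenExperiment(cnt, as.data.frame(gt[1:n, ]),
                           data.frame(sample = c("a", "b"),
                                      timepoint = c("PD0", "PD20"),
                                      treatment = "TMZ", genotype = "WT",
                                      replicate = 1))
    assays(se)$cpm <- cnt
    r <- pathwayPairedT(se, design, pseudocount = 0.5)
    dd <- log10(cnt[, 2] + 0.5) - log10(cnt[, 1] + 0.5)
    tt <- t.test(dd)
    expect_equal(r$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(r$neg_log10_p, -log10(tt$p.value), tolerance = 1e-10)
  }
})

test_that("paired-t is invariant to guide order (pairing by id)", {
  d <- smallDesign(4, 3, 10)
  se <- smallScreen(d, seed = 17, nReplicates = 2)
  r1 <- pathwayPairedT(se, d)
  se2 <- se[rev(seq_len(nrow(se))), ]
  r2 <- pathwayPairedT(se2, d)
  key <- function(x) x[order(x$genotype, x$treatment, x$pathway), ]
  expect_equal(key(r1), key(r2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("radar summary is complete with explicit NAs", {
  zres <- data.frame(genotype = c("WT", "WT"), pathway = c("HR", "TLS"),
                     z_p = c(1, 2), p_value = c(0.01, 0.2),
                     n_genes = 2L, n_excluded = 0L)
  drop <- data.frame(genotype = "WT", treatment = c("TMZ", "DMSO"),
                     pathway = "HR", n_pairs = 4L, t_stat = 0,
                     neg_log10_p = 0, log2_fc_pooled = c(-2, -0.5),
                     degenerate = FALSE)
  r <- radarSummary(zres, drop)
  expect_equal(nrow(r), 2)  # cell_lines x pathways
  expect_equal(r$neg_log10_p[r$pathway == "HR"], 2)
  expect_equal(r$log2_fc[r$pathway == "HR"], -1.5)
  expect_true(is.na(r$log2_fc[r$pathway == "TLS"]))  # explicit NA
})
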
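# End-to-end demo on synthetic data: generates inputs, writes every table in
# the package's TSV dialects, runs all three analysis arms and a small null
# calibration sub-run, and writes a text summary. Deterministic: the same
# seed gives byte-identical outputs.

#' Run the full pipeline on synthetic data
#'
#' Orchestrates all stages: (1) a dropout screen on the default 504-gene /
#' 5040-guide / 1000-NTC library with a handful of true depleted genes --
#' CPM normalization, guide log2 ratios, SigmaFC with permutation p-values,
#' per-gene Z contrasts, pathway Z-test, paired-t dropout table and radar
#' summary; (2) clone mutation catalogs for two genotypes x two treatments
#' (six clones each) with an alkylation-signature activity in the treated
#' arms -- variant filtering, catalog building, arm comparison, NNLS
#' signature refit and hypermutation calls; (3) a synthetic patient cohort --
#' proliferation adjustment, tertiles, logistic fit. A null screen sub-run
#' reports the empirical type-I error of the pathway Z-test. All stage
#' outputs are written as TSV under \code{outdir}; a human-readable
#' \code{summary.txt} collects headline numbers.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param outdir output directory (created if needed).
#' @param nGenes,guidesPerGene,nNTC library dimensions (defaults: the
#'   504 x 10 + 1000 design).
#' @param nullScreens screens in the pathway-Z calibration sub-run.
#' @param B permutation resamples for gene p-values.
#' @param cohortSize patients in the synthetic cohort.
#' @return (invisibly) a list with the main result tables.
#' @export
runDemo <- function(seed = 1L, outdir = "tmzmut_demo",
                    nGenes = 504L, guidesPerGene = 10L, nNTC = 1000L,
                    nullScreens = 25L, B = 1000L, cohortSize = 400L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, paste0(...))
  seed <- as.integer(seed)
  lines <- c("tmzmut demo run", sprintf("master seed: %d", seed), "")

  ## --- screen arm ---------------------------------------------------------
  design <- makeLibraryDesign(nGenes, guidesPerGene, nNTC)
  gt <- guideTable(design)
  lines <- c(lines, sprintf(
    "library: %d targeting guides over %d genes + %d non-targeting controls",
    sum(!gt$is_ntc), length(libraryGenes(design)), sum(gt$is_ntc)))
  genes <- libraryGenes(design)
  effects <- data.frame(gene_id = genes[seq_len(min(12, length(genes)))],
                        treatment = "TMZ",
                        effect = -0.25)
  screen <- simulateScreen(design, geneEffects = effects,
                           seed = seed + 11L)
  writeLibraryDesign(design, p("library.tsv"), p("pathways.tsv"))
  writeCountTable(screen, p("counts.tsv"), p("samples.tsv"))
  # re-read through the io layer so the demo exercises it end to end
  screen <- readCountTable(p("counts.tsv"), p("samples.tsv"),
                           readLibraryDesign(p("library.tsv"),
                                             p("pathways.tsv")))
  screen <- normalizeCounts(screen)
  lfcs <- guideLog2Ratios(screen)
  scores <- geneSigmaFC(lfcs, design)
  scores <- permutationPvalues(scores, lfcs, B = B, seed = seed + 13L)
  writeTsv(scores, p("gene_scores.tsv"))
  contr <- geneContrasts(lfcs)
  zres <- pathwayZstat(contr, pathwayMap(design))
  writeTsv(zres, p("pathway_z.tsv"))
  dropo <- pathwayPairedT(screen, design)
  writeTsv(dropo, p("pathway_paired_t.tsv"))
  radar <- radarSummary(zres, dropo)
  writeTsv(radar, p("radar_summary.tsv"))
  tmzScores <- scores[scores$treatment == "TMZ", ]
  hits <- tmzScores$gene_id[tmzScores$p_adj < 0.05 &
                              tmzScores$sigma_fc < 0]
  lines <- c(lines,
             sprintf("screen: %d/%d depleted genes at adjusted p < 0.05 (TMZ arm; %d true)",
                     length(hits), nrow(tmzScores), nrow(effects)),
             sprintf("pathway Z-test: min p = %.3g (%s)",
                     min(zres$p_value),
                     zres$pathway[which.min(zres$p_value)]))

  ## --- null calibration sub-run -------------------------------------------
  zNull <- unlist(lapply(seq_len(nullScreens), function(i) {
    s <- simulateScreen(design, seed = seed + 1000L + i)
    s <- normalizeCounts(s)
    pathwayZstat(geneContrasts(guideLog2Ratios(s)),
                 pathwayMap(design))$z_p
  }))
  typeI <- mean(abs(zNull) > stats::qnorm(0.975))
  lines <- c(lines, sprintf(
    "pathway Z null calibration: type-I error %.4f at alpha 0.05 (%d null pathways)",
    typeI, length(zNull)))

  ## --- mutagenesis arm ----------------------------------------------------
  sigs <- syntheticSignatures()
  writeSignatureMatrix(sigs, p("signatures.tsv"))
  arms <- expand.grid(genotype = c("RAD18_WT", "RAD18_KO"),
                      treatment = c("DMSO", "TMZ"),
                      stringsAsFactors = FALSE)
  arms$n_clones <- 6L
  K <- length(signatureNames(sigs))
  act <- sapply(seq_len(nrow(arms)), function(i) {
    a <- stats::setNames(numeric(K), signatureNames(sigs))
    a["Signature 1"] <- 60
    a["Signature 5"] <- 40
    if (arms$treatment[i] == "TMZ") a["Signature 11"] <- 400
    a
  })
  sim <- simulateCatalogs(arms, sigs, act, artifactsPerClone = 5L,
                          seed = seed + 21L)
  writeVariants(sim$variants, p("variants.tsv"))
  flt <- filterVariants(readVariants(p("variants.tsv")))
  writeTsv(data.frame(rule = names(flt$audit), n = as.integer(flt$audit)),
           p("filter_audit.tsv"))
  catalogs <- buildCatalogs(flt$kept,
                            as.data.frame(colData(sim$catalogs)))
  writeCatalogs(catalogs, p("catalogs.tsv"))
  induc <- compareArms(catalogs)
  writeTsv(induc, p("induction.tsv"))
  fits <- fitSignatures(catalogs, sigs)
  fits$is_hypermutated <-
    callHypermutation(fits[["Signature 11"]])$is_hypermutated
  writeTsv(fits, p("exposures.tsv"))
  tot <- induc[induc$class == "total", ]
  lines <- c(lines,
             sprintf("filter audit: %s",
                     paste(sprintf("%s=%d", names(flt$audit), flt$audit),
                           collapse = " ")),
             sprintf("TMZ-induced SNVs: %s",
                     paste(sprintf("%s %+0.1f (p=%.3g)", tot$genotype,
                                   tot$induced, tot$p_value),
                           collapse = "; ")),
             sprintf("hypermutated clones (Signature 11 > 500): %d/%d",
                     sum(fits$is_hypermutated), nrow(fits)))

  ## --- cohort arm ---------------------------------------------------------
  cohort <- simulateCohort(cohortSize, seed = seed + 31L)
  writeCohort(cohort, p("cohort.tsv"))
  adj <- adjustExpression(readCohort(p("cohort.tsv")))
  mfit <- fitHypermutationModel(adj)
  cf <- coef(mfit)
  writeTsv(data.frame(term = rownames(cf), cf), p("cohort_fit.tsv"))
  lines <- c(lines, sprintf(
    "cohort logistic fit (n=%d): rad18_adj %.3f (p=%.3g), mgmt %.3f (p=%.3g)",
    mfit@n, cf["rad18_adj", "estimate"], cf["rad18_adj", "p_value"],
    cf["mgmt", "estimate"], cf["mgmt", "p_value"]))

  writeLines(lines, p("summary.txt"))
  invisible(list(scores = scores, pathway_z = zres, dropouts = dropo,
                 radar = radar, type1 = typeI, audit = flt$audit,
                 catalogs = catalogs, induction = induc, exposures = fits,
                 cohort_fit = mfit, summary = lines))
}
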
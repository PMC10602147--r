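# Guide- and gene-level dropout statistics: CPM normalization, log2 PD20/PD0
# ratios, the SigmaFC gene score and its permutation null built from
# non-targeting control guides.

#' Counts-per-million normalization
#'
#' Scales every sample column to one million total counts, the normalization
#' under which all downstream ratios are depth-invariant.
#'
#' @param se A [ScreenExperiment-class] with raw counts.
#' @return The same object with an added \code{"cpm"} assay.
#' @export
normalizeCounts <- function(se) {
  m <- assay(se, "counts")
  depth <- colSums(m)
  if (any(depth == 0))
    stopf("cannot normalize: sample(s) with zero total counts: %s",
          paste(colnames(m)[depth == 0], collapse = ", "))
  cpm <- sweep(m, 2, depth, "/") * 1e6
  assays(se)$cpm <- cpm
  se
}

#' Per-guide log2 PD20/PD0 ratios
#'
#' For every (genotype, treatment, replicate) pair of matched PD0/PD20
#' samples, computes \code{log2((PD20_cpm + c) / (PD0_cpm + c))} per guide
#' with pseudocount \code{c}. Requires [normalizeCounts()] first.
#'
#' @param se A [ScreenExperiment-class] with a \code{"cpm"} assay.
#' @param pseudocount pseudocount \code{c} > 0 in CPM units (default 0.5).
#' @return data.frame with guide_id, gene_id, is_ntc, genotype, treatment,
#'   replicate, lfc.
#' @export
guideLog2Ratios <- function(se, pseudocount = 0.5) {
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  if (!"cpm" %in% assayNames(se))
    stopf("run normalizeCounts() first (no 'cpm' assay)")
  cpm <- assay(se, "cpm")
  cd <- as.data.frame(colData(se))
  key <- interaction(cd$genotype, cd$treatment, cd$replicate, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    idx <- which(key == k)
    i0 <- idx[cd$timepoint[idx] == "PD0"]
    i20 <- idx[cd$timepoint[idx] == "PD20"]
    if (length(i0) != 1L || length(i20) != 1L)
      stopf("unmatched PD0/PD20 samples for %s", k)
    rd <- as.data.frame(rowData(se))
    out[[k]] <- data.frame(
      guide_id = rownames(cpm),
      gene_id = rd$gene_id, is_ntc = rd$is_ntc,
      genotype = cd$genotype[i0], treatment = cd$treatment[i0],
      replicate = cd$replicate[i0],
      lfc = log2((cpm[, i20] + pseudocount) / (cpm[, i0] + pseudocount)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# replicate-mean lfc per guide within each (genotype, treatment)
replicateMeanLfc <- function(lfcs) {
  if (nrow(lfcs) == 0L)
    return(lfcs[c("guide_id", "gene_id", "is_ntc", "genotype",
                  "treatment", "lfc")])
  agg <- stats::aggregate(lfc ~ guide_id + gene_id + is_ntc +
                            genotype + treatment,
                          data = transform(lfcs,
                                           gene_id = ifelse(is.na(gene_id),
                                                            "<NTC>", gene_id)),
                          FUN = mean)
  agg$gene_id[agg$gene_id == "<NTC>"] <- NA_character_
  agg
}

#' SigmaFC gene scores
#'
#' The SigmaFC (SUMLFC) gene score: for each gene and condition, the sum over
#' the gene's guides of the guide's replicate-mean log2 PD20/PD0 ratio.
#' Non-targeting guides never contribute to gene scores. Genes in the design
#' with no guides present in \code{lfcs} are reported via a warning and
#' omitted.
#'
#' @param lfcs data.frame from [guideLog2Ratios()].
#' @param design A [LibraryDesign-class].
#' @return data.frame with genotype, treatment, gene_id, sigma_fc, n_guides.
#' @export
geneSigmaFC <- function(lfcs, design) {
  gt <- as.data.frame(guideTable(design))
  unknown <- setdiff(lfcs$guide_id, gt$guide_id)
  if (length(unknown))
    stopf("lfcs contain guides absent from the design, e.g. %s", unknown[1])
  g <- replicateMeanLfc(lfcs[!lfcs$is_ntc, , drop = FALSE])
  if (nrow(g) == 0L)
    return(data.frame(genotype = character(0), treatment = character(0),
                      gene_id = character(0), sigma_fc = numeric(0),
                      n_guides = integer(0)))
  res <- stats::aggregate(lfc ~ genotype + treatment + gene_id, data = g,
                          FUN = function(x) c(sum = sum(x), n = length(x)))
  out <- data.frame(genotype = res$genotype, treatment = res$treatment,
                    gene_id = res$gene_id,
                    sigma_fc = res$lfc[, "sum"],
                    n_guides = as.integer(res$lfc[, "n"]))
  absent <- setdiff(libraryGenes(design), out$gene_id)
  if (length(absent))
    warning(sprintf("%d gene(s) had no guides in the data and were omitted",
                    length(absent)), call. = FALSE)
  out[order(out$genotype, out$treatment, out$gene_id), ]
}

#' Permutation p-values against non-targeting controls
#'
#' For each gene with \code{n} guides, the null SigmaFC distribution is built
#' by \code{B} resamples (with replacement) of \code{n} non-targeting guide
#' replicate-mean lfcs, summed. Two-sided add-one p-value:
#' \code{p = (1 + #\{|null| >= |sigma_fc|\}) / (B + 1)}, so p is never 0 and
#' never exceeds 1. Benjamini-Hochberg adjustment is applied across genes
#' within each (genotype, treatment).
#'
#' @param scores data.frame from [geneSigmaFC()].
#' @param lfcs data.frame from [guideLog2Ratios()] (must include the NTC
#'   guides; >= 30 required).
#' @param B number of resamples (>= 100; default 1000).
#' @param seed integer seed; identical seeds give identical p-values.
#' @return \code{scores} with added columns p_perm and p_adj.
#' @export
permutationPvalues <- function(scores, lfcs, B = 1000L, seed = 1L) {
  if (B < 100) stopf("B must be >= 100")
  ntc <- replicateMeanLfc(lfcs[lfcs$is_ntc, , drop = FALSE])
  if (nrow(ntc) == 0L) stopf("no non-targeting (NTC) guides in lfcs")
  scores$p_perm <- NA_real_
  withSeed(seed, {
    grp <- interaction(scores$genotype, scores$treatment, drop = TRUE)
    for (k in levels(grp)) {
      idx <- which(grp == k)
      pool <- ntc$lfc[ntc$genotype == scores$genotype[idx[1]] &
                        ntc$treatment == scores$treatment[idx[1]]]
      if (length(pool) < 30)
        stopf("fewer than 30 NTC guides available for %s", k)
      for (i in idx) {
        n <- scores$n_guides[i]
        nullSigma <- rowSums(matrix(sample(pool, B * n, replace = TRUE),
                                    nrow = B, ncol = n))
        scores$p_perm[i] <-
          (1 + sum(abs(nullSigma) >= abs(scores$sigma_fc[i]))) / (B + 1)
      }
      scores$p_adj[idx] <- stats::p.adjust(scores$p_perm[idx],
                                           method = "BH")
    }
  })
  scores
}
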
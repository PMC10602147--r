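# Pathway-level dropout statistics: per-gene TMZ-vs-DMSO Z contrasts, the
# combined pathway Z-test (standard-normal null), and the paired-t dropout
# statistic on pooled log10 counts.

#' Two-sample Z contrast for one gene
#'
#' \eqn{X_g} is the difference of sample means (TMZ - DMSO) of guide-level
#' log2 PD20/PD0 ratios, \eqn{S_g} its standard error
#' \eqn{\sqrt{s_1^2/n_1 + s_2^2/n_2}} with unbiased variances, and
#' \eqn{Z_g = X_g / S_g}. With both arms constant and equal, \eqn{S_g = 0}
#' and \eqn{Z_g} is returned as \code{NA} (flagged degenerate).
#'
#' @param tmz,dmso numeric vectors of log2 ratios (>= 2 values each).
#' @return one-row data.frame: x_g, s_g, z_g, n_tmz, n_dmso, degenerate.
#' @export
geneZstat <- function(tmz, dmso) {
  if (length(tmz) < 2 || length(dmso) < 2)
    stopf("need >= 2 values per arm")
  x <- mean(tmz) - mean(dmso)
  s <- sqrt(stats::var(tmz) / length(tmz) + stats::var(dmso) / length(dmso))
  data.frame(x_g = x, s_g = s,
             z_g = if (s > 0) x / s else NA_real_,
             n_tmz = length(tmz), n_dmso = length(dmso),
             degenerate = s == 0)
}

#' Per-gene Z contrasts for a whole screen
#'
#' Applies [geneZstat()] to every gene within each genotype, contrasting the
#' two treatment arms. The replication unit is switchable: \code{"both"}
#' (default) uses every guide x replicate lfc, \code{"guides"} first averages
#' replicates within guide, \code{"replicates"} first averages guides within
#' replicate.
#'
#' @param lfcs data.frame from [guideLog2Ratios()] covering both treatments.
#' @param unit replication unit (see above).
#' @param treatmentCase name of the treated arm (default "TMZ"); the other
#'   arm is the control.
#' @return data.frame with genotype, gene_id, x_g, s_g, z_g, n_tmz, n_dmso,
#'   degenerate.
#' @export
geneContrasts <- function(lfcs, unit = c("both", "guides", "replicates"),
                          treatmentCase = "TMZ") {
  unit <- match.arg(unit)
  lf <- lfcs[!lfcs$is_ntc, , drop = FALSE]
  trts <- unique(lf$treatment)
  if (!treatmentCase %in% trts || length(trts) != 2L)
    stopf("need exactly two treatment arms including '%s'", treatmentCase)
  if (unit == "guides") {
    lf <- replicateMeanLfc(lf)
  } else if (unit == "replicates") {
    lf <- stats::aggregate(lfc ~ gene_id + genotype + treatment + replicate,
                           data = lf, FUN = mean)
  }
  out <- list()
  for (gty in unique(lf$genotype)) {
    armStats <- function(trt) {
      d <- lf[lf$genotype == gty & lf$treatment == trt, ]
      f <- factor(d$gene_id)
      n <- as.vector(table(f))
      s1 <- rowsum(d$lfc, f)[, 1]
      s2 <- rowsum(d$lfc^2, f)[, 1]
      mu <- s1 / n
      list(gene = levels(f), n = n, mean = mu,
           var = (s2 - n * mu^2) / pmax(n - 1, 1))
    }
    a <- armStats(treatmentCase)
    ctl <- setdiff(trts, treatmentCase)
    b <- armStats(ctl)
    genes <- intersect(a$gene, b$gene)
    ia <- match(genes, a$gene); ib <- match(genes, b$gene)
    x <- a$mean[ia] - b$mean[ib]
    s <- sqrt(a$var[ia] / a$n[ia] + b$var[ib] / b$n[ib])
    s[pmin(a$n[ia], b$n[ib]) < 2] <- NA_real_
    out[[gty]] <- data.frame(
      genotype = gty, gene_id = genes, x_g = x, s_g = s,
      z_g = ifelse(s > 0, x / s, NA_real_),
      n_tmz = a$n[ia], n_dmso = b$n[ib],
      degenerate = !is.na(s) & s == 0)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Combined pathway Z-test
#'
#' Combines gene contrasts within each pathway as
#' \eqn{Z_P = \sum_g X_g / \sqrt{\sum_g S_g^2}}, standard normal under the
#' null of no differential dropout, with two-sided p-value
#' \eqn{2(1 - \Phi(|Z_P|))}. Genes with \eqn{S_g = 0} (or undefined) carry no
#' sampling-noise information; they are excluded with a warning and counted
#' in \code{n_excluded}.
#'
#' @param contrasts data.frame from [geneContrasts()] (or one [geneZstat()]
#'   row per gene plus gene_id/genotype columns).
#' @param pathwayMap named list \code{gene_id -> pathways} (e.g.
#'   [pathwayMap()]); \code{NULL} pools all genes into one pathway
#'   \code{"all"}.
#' @return data.frame with genotype, pathway, z_p, p_value, n_genes,
#'   n_excluded.
#' @export
pathwayZstat <- function(contrasts, pathwayMap = NULL) {
  if (is.null(pathwayMap)) {
    pathwayMap <- stats::setNames(rep(list("all"),
                                      length(unique(contrasts$gene_id))),
                                  unique(contrasts$gene_id))
  }
  memb <- data.frame(
    gene_id = rep(names(pathwayMap), lengths(pathwayMap)),
    pathway = unlist(pathwayMap, use.names = FALSE))
  df <- merge(contrasts, memb, by = "gene_id")
  if (nrow(df) == 0L) stopf("no genes matched the pathway map")
  bad <- is.na(df$s_g) | df$s_g == 0
  if (any(bad))
    warning(sprintf("%d gene-pathway entr%s with S_g = 0 or undefined excluded",
                    sum(bad), if (sum(bad) == 1) "y" else "ies"),
            call. = FALSE)
  kept <- df[!bad, , drop = FALSE]
  empty <- setdiff(paste(df$genotype, df$pathway),
                   paste(kept$genotype, kept$pathway))
  if (length(empty))
    stopf("pathway(s) empty after exclusions: %s",
          paste(empty, collapse = ", "))
  kgrp <- paste(kept$genotype, kept$pathway, sep = "\r")
  sx <- rowsum(kept$x_g, kgrp)
  lev <- rownames(sx)
  ss2 <- rowsum(kept$s_g^2, kgrp)[lev, 1]
  n <- as.vector(table(kgrp)[lev])
  first <- match(lev, kgrp)
  allgrp <- paste(df$genotype, df$pathway, sep = "\r")
  nexc <- as.vector(table(factor(allgrp[bad], levels = lev)))
  z <- sx[, 1] / sqrt(ss2)
  res <- data.frame(genotype = kept$genotype[first],
                    pathway = kept$pathway[first],
                    z_p = z,
                    p_value = 2 * stats::pnorm(-abs(z)),
                    n_genes = n, n_excluded = nexc)
  rownames(res) <- NULL
  res[order(res$genotype, res$pathway), ]
}

#' Paired-t pathway dropout statistic
#'
#' For each pathway and condition (genotype x treatment), pools the guides of
#' the pathway's genes and pairs \code{log10(cpm + c)} at PD20 against PD0
#' per (guide, replicate) unit. Reports the paired t statistic, the two-sided
#' \code{-log10(p)} (df = n_pairs - 1) and the log2 ratio of pooled PD20 to
#' pooled PD0 counts. Zero-variance differences are flagged degenerate with
#' p = 1.
#'
#' @param se A [ScreenExperiment-class] with a \code{"cpm"} assay.
#' @param design A [LibraryDesign-class].
#' @param pseudocount pseudocount in CPM units (> 0, default 0.5).
#' @return data.frame with genotype, treatment, pathway, n_pairs, t_stat,
#'   neg_log10_p, log2_fc_pooled, degenerate.
#' @export
pathwayPairedT <- function(se, design, pseudocount = 0.5) {
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  if (!"cpm" %in% assayNames(se))
    stopf("run normalizeCounts() first (no 'cpm' assay)")
  cpm <- assay(se, "cpm")
  cd <- as.data.frame(colData(se))
  pmap <- pathwayMap(design)
  gt <- as.data.frame(guideTable(design))
  memb <- data.frame(gene_id = rep(names(pmap), lengths(pmap)),
                     pathway = unlist(pmap, use.names = FALSE))
  out <- list()
  conds <- unique(cd[c("genotype", "treatment")])
  for (ci in seq_len(nrow(conds))) {
    gty <- conds$genotype[ci]; trt <- conds$treatment[ci]
    sel <- cd$genotype == gty & cd$treatment == trt
    reps <- sort(unique(cd$replicate[sel]))
    for (pw in unique(memb$pathway)) {
      genes <- memb$gene_id[memb$pathway == pw]
      guides <- gt$guide_id[!gt$is_ntc & gt$gene_id %in% genes]
      guides <- intersect(guides, rownames(cpm))
      if (!length(guides)) next
      x20 <- c(); x0 <- c()
      for (r in reps) {
        i0 <- which(sel & cd$replicate == r & cd$timepoint == "PD0")
        i20 <- which(sel & cd$replicate == r & cd$timepoint == "PD20")
        if (length(i0) != 1L || length(i20) != 1L)
          stopf("unmatched PD0/PD20 samples for %s/%s replicate %s",
                gty, trt, r)
        x0 <- c(x0, cpm[guides, i0])
        x20 <- c(x20, cpm[guides, i20])
      }
      if (length(x0) < 2) stopf("pathway %s has < 2 pairs", pw)
      d <- log10(x20 + pseudocount) - log10(x0 + pseudocount)
      degen <- stats::sd(d) == 0
      if (degen) {
        tstat <- 0; p <- 1
      } else {
        tt <- stats::t.test(d)
        tstat <- unname(tt$statistic); p <- tt$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        genotype = gty, treatment = trt, pathway = pw,
        n_pairs = length(d), t_stat = tstat,
        neg_log10_p = -log10(p),
        log2_fc_pooled = log2(sum(x20) / sum(x0)),
        degenerate = degen)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Long-format radar-plot summary
#'
#' Joins the pathway Z-test results with the pooled dropout fold changes into
#' one row per (cell line, pathway): \code{-log10(p)} of the combined Z-test
#' and the TMZ-minus-control difference of pooled log2 fold changes. Missing
#' combinations appear as explicit \code{NA} rows, never silently dropped.
#'
#' @param zres data.frame from [pathwayZstat()] (genotype = cell line).
#' @param dropouts data.frame from [pathwayPairedT()].
#' @param treatmentCase treated arm name (default "TMZ").
#' @return data.frame with cell_line, pathway, neg_log10_p, log2_fc.
#' @export
radarSummary <- function(zres, dropouts, treatmentCase = "TMZ") {
  cellLines <- unique(c(zres$genotype, dropouts$genotype))
  pathways <- unique(c(zres$pathway, dropouts$pathway))
  grid <- expand.grid(cell_line = cellLines, pathway = pathways,
                      stringsAsFactors = FALSE)
  mz <- match(paste(grid$cell_line, grid$pathway),
              paste(zres$genotype, zres$pathway))
  grid$neg_log10_p <- -log10(zres$p_value[mz])
  fcOf <- function(trt) {
    d <- dropouts[dropouts$treatment == trt, ]
    d$log2_fc_pooled[match(paste(grid$cell_line, grid$pathway),
                           paste(d$genotype, d$pathway))]
  }
  ctl <- setdiff(unique(dropouts$treatment), treatmentCase)
  grid$log2_fc <- if (length(ctl) == 1L)
    fcOf(treatmentCase) - fcOf(ctl) else fcOf(treatmentCase)
  grid
}
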
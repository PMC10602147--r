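# Variant filtering cascade, pyrimidine-strand SNV classification, per-clone
# catalog construction and TMZ-vs-control arm comparisons.

#' Filter configuration
#'
#' Thresholds of the post-calling filter cascade. Boundary semantics are
#' inclusive: an indel of exactly \code{maxIndelLen} bases is kept (only
#' longer ones are removed), and records at exactly \code{minMaf},
#' \code{minDepth} or \code{minAltReads} are kept. The coverage rule applies
#' jointly to tumor and normal depths.
#'
#' @param maxIndelLen longest indel kept (default 10).
#' @param minMaf minimum mutant allele frequency (default 0.10).
#' @param minDepth minimum coverage in both tumor and normal (default 10).
#' @param minAltReads minimum mutation-supporting reads in tumor (default 3).
#' @param dropKnownPolymorphisms remove known polymorphisms (default TRUE).
#' @param requireExomeInterval keep only records inside the exome capture
#'   intervals (default TRUE).
#' @return list of class \code{"filter_config"}.
#' @export
filterConfig <- function(maxIndelLen = 10L, minMaf = 0.10, minDepth = 10L,
                         minAltReads = 3L, dropKnownPolymorphisms = TRUE,
                         requireExomeInterval = TRUE) {
  if (maxIndelLen < 0 || minDepth < 0 || minAltReads < 0)
    stopf("filter thresholds must be non-negative")
  if (minMaf < 0 || minMaf > 1) stopf("minMaf must lie in [0, 1]")
  structure(list(maxIndelLen = maxIndelLen, minMaf = minMaf,
                 minDepth = minDepth, minAltReads = minAltReads,
                 dropKnownPolymorphisms = dropKnownPolymorphisms,
                 requireExomeInterval = requireExomeInterval),
            class = "filter_config")
}

FILTER_RULES <- c("indel_gt_max", "low_maf", "low_depth", "few_alt_reads",
                  "known_polymorphism", "outside_exome")

#' Apply the variant filter cascade
#'
#' Rules are applied in order: (1) indels longer than \code{maxIndelLen};
#' (2) allele frequency, then coverage (tumor AND normal), then supporting
#' reads; (3) known polymorphisms; then the exome-interval mask. Each removed
#' record is attributed to the FIRST rule it fails, so the audit counts plus
#' the kept count always sum to the input size. Filtering kept records again
#' removes nothing (the cascade is idempotent).
#'
#' @param variants data.frame of variant records (see [readVariants()]).
#' @param cfg A [filterConfig()].
#' @return list with \code{kept} (data.frame) and \code{audit} (named
#'   integer vector over the rules plus \code{kept}).
#' @export
filterVariants <- function(variants, cfg = filterConfig()) {
  n <- nrow(variants)
  if (n == 0L) {
    audit <- stats::setNames(integer(length(FILTER_RULES) + 1L),
                             c(FILTER_RULES, "kept"))
    return(list(kept = variants, audit = audit))
  }
  indelLen <- abs(nchar(variants$ref) - nchar(variants$alt))
  fails <- cbind(
    indel_gt_max = variants$variant_type != "SNV" &
      indelLen > cfg$maxIndelLen,
    low_maf = variants$maf < cfg$minMaf,
    low_depth = variants$depth_tumor < cfg$minDepth |
      variants$depth_normal < cfg$minDepth,
    few_alt_reads = variants$alt_reads < cfg$minAltReads,
    known_polymorphism = cfg$dropKnownPolymorphisms &
      variants$known_polymorphism,
    outside_exome = cfg$requireExomeInterval & !variants$in_exome_interval)
  firstFail <- apply(fails, 1, function(f) {
    w <- which(f)
    if (length(w)) w[1] else 0L
  })
  audit <- stats::setNames(
    vapply(seq_along(FILTER_RULES), function(i) sum(firstFail == i),
           integer(1)), FILTER_RULES)
  audit <- c(audit, kept = sum(firstFail == 0L))
  list(kept = variants[firstFail == 0L, , drop = FALSE], audit = audit)
}

#' Classify an SNV into substitution class and 96-context label
#'
#' Pyrimidine-strand convention: when the reference base is a purine (A or
#' G), ref, alt and the trinucleotide context are reverse-complemented before
#' labelling, so a variant and its reverse-complement representation classify
#' identically. Records with ambiguous bases (N) yield \code{NA} and a
#' warning.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @param context 3-mer context centred on the variant (middle base = ref).
#' @return data.frame with \code{class} (one of C>A, C>G, C>T, T>A, T>C,
#'   T>G) and \code{label} (\code{X[R>A]Y}).
#' @export
classifySNV <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  ok <- nchar(ref) == 1L & nchar(alt) == 1L & nchar(context) == 3L &
    ref != alt & substr(context, 2, 2) == ref &
    !grepl("N", paste0(ref, alt, context))
  if (any(!ok))
    warning(sprintf("%d record(s) with ambiguous or inconsistent bases skipped",
                    sum(!ok)), call. = FALSE)
  r <- ref; a <- alt; ctx <- context
  pur <- ok & r %in% c("A", "G")
  if (any(pur)) {
    ctx[pur] <- revComp(ctx[pur])
    r[pur] <- revComp(r[pur])
    a[pur] <- revComp(a[pur])
  }
  cls <- ifelse(ok, paste0(r, ">", a), NA_character_)
  lab <- ifelse(ok,
                paste0(substr(ctx, 1, 1), "[", cls, "]", substr(ctx, 3, 3)),
                NA_character_)
  data.frame(class = cls, label = lab)
}

#' Build per-clone mutation catalogs
#'
#' Bins each clone's kept SNVs (non-SNV records are ignored) into the 96
#' pyrimidine-centred context bins. Clones listed in \code{cloneInfo} but
#' carrying zero SNVs get valid all-zero catalogs.
#'
#' @param variants data.frame of (filtered) variant records with
#'   \code{clone_id}.
#' @param cloneInfo data.frame with \code{clone_id}, \code{genotype},
#'   \code{treatment}; \code{NULL} derives clone ids from the variants (arm
#'   labels then must be columns of \code{variants}).
#' @return A [CatalogExperiment-class].
#' @export
buildCatalogs <- function(variants, cloneInfo = NULL) {
  if (is.null(cloneInfo)) {
    requireColumns(variants, c("clone_id", "genotype", "treatment"),
                   "variants")
    cloneInfo <- unique(variants[c("clone_id", "genotype", "treatment")])
  }
  cloneInfo <- as.data.frame(cloneInfo)
  labs <- contextLabels96()
  snv <- variants[variants$variant_type == "SNV", , drop = FALSE]
  cl <- classifySNV(snv$ref, snv$alt, snv$context)
  keep <- !is.na(cl$label)
  m <- matrix(0L, 96L, nrow(cloneInfo),
              dimnames = list(labs, cloneInfo$clone_id))
  if (any(keep)) {
    tab <- table(factor(cl$label[keep], levels = labs),
                 factor(snv$clone_id[keep], levels = cloneInfo$clone_id))
    m <- m + as.matrix(unclass(tab))
  }
  CatalogExperiment(m, cloneInfo)
}

#' Compare treated and control arms
#'
#' Per genotype, the TMZ-induced mutation load: difference of arm means of
#' per-clone SNV counts (total and, optionally, per substitution class),
#' with a two-sided Welch t-test. C>T is labelled Pattern I (the
#' O6-methylguanine-driven class); the other five classes are Pattern II.
#' Arms with a single clone report the induced difference with \code{p = NA};
#' identical constant arms are degenerate with p = 1.
#'
#' @param catalogs A [CatalogExperiment-class].
#' @param perClass also return per-substitution-class rows (default TRUE).
#' @param treatmentCase treated arm label (default "TMZ").
#' @return data.frame with genotype, class ("total" or a substitution
#'   class), pattern, mean_tmz, mean_dmso, induced, p_value.
#' @export
compareArms <- function(catalogs, perClass = TRUE, treatmentCase = "TMZ") {
  cd <- as.data.frame(colData(catalogs))
  ctl <- setdiff(unique(cd$treatment), treatmentCase)
  if (length(ctl) != 1L)
    stopf("need exactly two treatment arms including '%s'", treatmentCase)
  counts <- rbind(total = totalSNV(catalogs),
                  if (perClass) classCounts(catalogs))
  out <- list()
  for (gty in unique(cd$genotype)) {
    for (k in rownames(counts)) {
      a <- counts[k, cd$genotype == gty & cd$treatment == treatmentCase]
      b <- counts[k, cd$genotype == gty & cd$treatment == ctl]
      p <- if (length(a) < 2 || length(b) < 2) NA_real_
      else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else NA_real_
      } else stats::t.test(a, b)$p.value
      out[[length(out) + 1L]] <- data.frame(
        genotype = gty, class = k,
        pattern = if (k == "total") NA_character_
                  else if (k == "C>T") "Pattern I" else "Pattern II",
        mean_tmz = mean(a), mean_dmso = mean(b),
        induced = mean(a) - mean(b), p_value = p)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
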
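# Readers and writers for every external table the pipeline touches.
# Dialect: tab-separated, '#' comments, UTF-8, no quoting. Coordinates are
# 1-based as in VCF.

# ---------------------------------------------------------------------------
# Library design + pathway map

#' Read / write a library design
#'
#' Library TSV columns: \code{guide_id}, \code{gene_id} (empty or \code{NA}
#' for controls), \code{is_ntc} (TRUE/FALSE). The pathway map is stored
#' separately (see [readPathwayMap()]).
#'
#' @param path file path.
#' @param pathwayPath optional pathway TSV merged into the design.
#' @return A [LibraryDesign-class].
#' @export
readLibraryDesign <- function(path, pathwayPath = NULL) {
  df <- readTsv(path)
  requireColumns(df, c("guide_id", "gene_id", "is_ntc"), basename(path))
  df$gene_id[df$gene_id %in% c("", "NA")] <- NA_character_
  df$is_ntc <- as.logical(df$is_ntc)
  if (anyDuplicated(df$guide_id))
    stopf("%s: duplicate guide_id '%s'", basename(path),
          df$guide_id[anyDuplicated(df$guide_id)])
  pmap <- if (is.null(pathwayPath)) {
    stats::setNames(rep(list(character(0)),
                        length(unique(stats::na.omit(df$gene_id)))),
                    unique(stats::na.omit(df$gene_id)))
  } else readPathwayMap(pathwayPath)
  new("LibraryDesign", guides = DataFrame(df, row.names = df$guide_id),
      pathways = pmap)
}

#' @rdname readLibraryDesign
#' @param design A [LibraryDesign-class].
#' @export
writeLibraryDesign <- function(design, path, pathwayPath = NULL) {
  writeTsv(as.data.frame(guideTable(design)), path)
  if (!is.null(pathwayPath)) writePathwayMap(pathwayMap(design), pathwayPath)
  invisible(path)
}

#' Read / write a gene-to-pathway map
#'
#' TSV with columns \code{gene_id}, \code{pathway}; a gene listed on several
#' rows belongs to several pathways and all memberships are preserved.
#'
#' @param path file path.
#' @return named list \code{gene_id -> character vector of pathways}.
#' @export
readPathwayMap <- function(path) {
  df <- readTsv(path)
  requireColumns(df, c("gene_id", "pathway"), basename(path))
  split(df$pathway, df$gene_id)
}

#' @rdname readPathwayMap
#' @param pmap named list as returned by [pathwayMap()].
#' @export
writePathwayMap <- function(pmap, path) {
  df <- data.frame(gene_id = rep(names(pmap), lengths(pmap)),
                   pathway = unlist(pmap, use.names = FALSE))
  writeTsv(df, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Counts + sample sheet

#' Read / write screen count tables
#'
#' Counts TSV: \code{guide_id} column plus one non-negative integer column
#' per sample. Sample-sheet TSV: \code{sample}, \code{timepoint} (PD0/PD20),
#' \code{treatment}, \code{genotype}, \code{replicate}. When a
#' \code{design} is supplied, guides unknown to it are reported and the file
#' rejected.
#'
#' @param path counts TSV path.
#' @param samplePath sample-sheet TSV path.
#' @param design optional [LibraryDesign-class] used for validation and to
#'   annotate rows; without it, guide/gene annotation is taken from the
#'   guide_id alone (all guides treated as targeting, gene unknown).
#' @return A [ScreenExperiment-class].
#' @export
readCountTable <- function(path, samplePath, design = NULL) {
  df <- readTsv(path)
  requireColumns(df, "guide_id", basename(path))
  if (ncol(df) < 2) stopf("%s: no sample columns found", basename(path))
  dup <- df$guide_id[duplicated(df$guide_id)]
  if (length(dup))
    stopf("%s: duplicate guide_id '%s'", basename(path), dup[1])
  m <- as.matrix(df[setdiff(names(df), "guide_id")])
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stopf("%s: non-numeric count values", basename(path))
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stopf("%s: negative count at row %d (guide '%s'), column '%s'",
          basename(path), neg[1, 1], df$guide_id[neg[1, 1]],
          colnames(m)[neg[1, 2]])
  rownames(m) <- df$guide_id
  sheet <- readTsv(samplePath)
  requireColumns(sheet,
                 c("sample", "timepoint", "treatment", "genotype",
                   "replicate"), basename(samplePath))
  missingSamples <- setdiff(colnames(m), sheet$sample)
  if (length(missingSamples))
    stopf("%s: sample sheet lacks column(s): %s", basename(samplePath),
          paste(missingSamples, collapse = ", "))
  if (!is.null(design)) {
    gt <- as.data.frame(guideTable(design))
    unknown <- setdiff(rownames(m), gt$guide_id)
    if (length(unknown))
      stopf("%s: %d guide(s) not in the library design, e.g. %s",
            basename(path), length(unknown),
            paste(utils::head(unknown, 5), collapse = ", "))
    gi <- gt[match(rownames(m), gt$guide_id), ]
  } else {
    gi <- data.frame(guide_id = rownames(m), gene_id = NA_character_,
                     is_ntc = FALSE)
  }
  ScreenExperiment(m, gi, sheet)
}

#' @rdname readCountTable
#' @param se A [ScreenExperiment-class].
#' @export
writeCountTable <- function(se, path, samplePath) {
  m <- assay(se, "counts")
  writeTsv(data.frame(guide_id = rownames(m), m, check.names = FALSE), path)
  cd <- as.data.frame(colData(se))
  writeTsv(cd[c("sample", "timepoint", "treatment", "genotype", "replicate")],
           samplePath)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Variant records

VARIANT_COLUMNS <- c("clone_id", "chrom", "pos", "ref", "alt",
                     "variant_type", "maf", "depth_tumor", "depth_normal",
                     "alt_reads", "context", "known_polymorphism",
                     "in_exome_interval")

validateVariants <- function(df, what = "variants") {
  requireColumns(df, setdiff(VARIANT_COLUMNS, "clone_id"), what)
  if (!"clone_id" %in% names(df)) df$clone_id <- NA_character_
  df$known_polymorphism <- as.logical(df$known_polymorphism)
  df$in_exome_interval <- as.logical(df$in_exome_interval)
  snv <- df$variant_type == "SNV"
  if (any(snv & (nchar(df$ref) != 1L | nchar(df$alt) != 1L)))
    stopf("%s: SNV records must have single-base ref and alt", what)
  bad <- snv & substr(df$context, 2, 2) != df$ref
  if (any(bad))
    stopf("%s: SNV at %s:%d has context '%s' whose middle base != ref '%s'",
          what, df$chrom[bad][1], df$pos[bad][1], df$context[bad][1],
          df$ref[bad][1])
  if (any(!snv & abs(nchar(df$ref) - nchar(df$alt)) < 1L))
    stopf("%s: indel records must change allele length", what)
  if (any(df$maf < 0 | df$maf > 1))
    stopf("%s: maf must lie in [0, 1]", what)
  if (any(df$depth_tumor < 0 | df$depth_normal < 0 | df$alt_reads < 0))
    stopf("%s: depths and supporting reads must be non-negative", what)
  df[union("clone_id", names(df))]
}

#' Read / write variant records
#'
#' Two on-disk forms are accepted: the pipeline's TSV dialect with every
#' field explicit, or a minimal VCF v4.2 subset (\code{.vcf} extension)
#' downstream of a Mutect2-style caller. The VCF form uses REF/ALT, per-
#' sample FORMAT fields \code{AF} (tumor MAF), \code{DP} (tumor and normal
#' depths) and \code{AD} (tumor alt-supporting reads, taken as
#' \code{AD[2]}), and INFO fields \code{CTX} (trinucleotide context),
#' \code{KP} (known-polymorphism flag) and \code{EXON} (exome-interval
#' flag). Sample columns named \code{TUMOR} and \code{NORMAL} are preferred;
#' with other names the first sample is the tumor.
#'
#' @param path file path (\code{.vcf} triggers the VCF reader).
#' @param cloneId clone label attached to VCF records (one VCF per clone).
#' @return data.frame of validated variant records.
#' @export
readVariants <- function(path, cloneId = NA_character_) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE))
    return(readVariantsVcf(path, cloneId))
  df <- readTsv(path)
  validateVariants(df, basename(path))
}

#' @rdname readVariants
#' @param variants data.frame of variant records.
#' @export
writeVariants <- function(variants, path) {
  writeTsv(validateVariants(variants, "variants"), path)
  invisible(path)
}

variantTypeOf <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

readVariantsVcf <- function(path, cloneId = NA_character_) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  gt <- VariantAnnotation::geno(vcf)
  missingTags <- setdiff(c("AF", "DP", "AD"), names(gt))
  if (length(missingTags))
    stopf("%s: VCF lacks required FORMAT field(s): %s", basename(path),
          paste(missingTags, collapse = ", "))
  samples <- colnames(gt$DP)
  tumor <- if ("TUMOR" %in% samples) "TUMOR" else samples[1]
  normal <- if ("NORMAL" %in% samples) "NORMAL" else
    if (length(samples) > 1) samples[2] else tumor
  info <- VariantAnnotation::info(vcf)
  if (n == 0L) {
    return(validateVariants(stats::setNames(
      data.frame(character(0), character(0), integer(0), character(0),
                 character(0), character(0), numeric(0), integer(0),
                 integer(0), integer(0), character(0), logical(0),
                 logical(0)), VARIANT_COLUMNS), basename(path)))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  if (length(alt) != n)
    stopf("%s: multi-allelic records are not supported", basename(path))
  ref <- as.character(VariantAnnotation::ref(vcf))
  ctx <- if ("CTX" %in% names(info)) as.character(info$CTX) else
    stopf("%s: VCF lacks required INFO field CTX (trinucleotide context)",
          basename(path))
  af <- gt$AF
  afT <- vapply(seq_len(n), function(i) as.numeric(af[[i, tumor]][1]),
                numeric(1))
  adT <- vapply(seq_len(n), function(i) {
    v <- gt$AD[[i, tumor]]
    as.integer(v[min(2L, length(v))])
  }, integer(1))
  df <- data.frame(
    clone_id = cloneId,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt,
    variant_type = variantTypeOf(ref, alt),
    maf = afT,
    depth_tumor = as.integer(gt$DP[, tumor]),
    depth_normal = as.integer(gt$DP[, normal]),
    alt_reads = adT,
    context = ctx,
    known_polymorphism = if ("KP" %in% names(info)) info$KP else FALSE,
    in_exome_interval = if ("EXON" %in% names(info)) info$EXON else TRUE)
  validateVariants(df, basename(path))
}

# ---------------------------------------------------------------------------
# Signature matrices

#' Read / write a signature matrix
#'
#' TSV layout: a \code{context} column of 96 labels (\code{X[R>A]Y},
#' pyrimidine-centred) plus one non-negative column per signature. Columns
#' whose sums are within 1e-3 of 1 are renormalized; anything further off,
#' a wrong row count, negative entries or duplicate names are rejected.
#'
#' @param path file path.
#' @return A [SignatureSet-class].
#' @export
readSignatureMatrix <- function(path) {
  df <- readTsv(path)
  requireColumns(df, "context", basename(path))
  if (nrow(df) != 96L)
    stopf("%s: expected 96 context rows, got %d", basename(path), nrow(df))
  m <- as.matrix(df[setdiff(names(df), "context")])
  storage.mode(m) <- "numeric"
  rownames(m) <- df$context
  if (anyDuplicated(colnames(m)))
    stopf("%s: duplicate signature names", basename(path))
  if (any(m < 0)) stopf("%s: negative signature entries", basename(path))
  SignatureSet(m)
}

#' @rdname readSignatureMatrix
#' @param sigs A [SignatureSet-class].
#' @export
writeSignatureMatrix <- function(sigs, path) {
  p <- signatureProbs(sigs)
  writeTsv(data.frame(context = rownames(p), p, check.names = FALSE), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Catalogs

#' Read / write mutation catalogs
#'
#' One row per clone: \code{clone_id}, \code{genotype}, \code{treatment},
#' then the 96 context columns in [contextLabels96()] order.
#'
#' @param path file path.
#' @return A [CatalogExperiment-class].
#' @export
readCatalogs <- function(path) {
  df <- readTsv(path)
  requireColumns(df, c("clone_id", "genotype", "treatment"), basename(path))
  labs <- contextLabels96()
  requireColumns(df, labs, basename(path))
  m <- t(as.matrix(df[labs]))
  CatalogExperiment(m, df[c("clone_id", "genotype", "treatment")])
}

#' @rdname readCatalogs
#' @param catalogs A [CatalogExperiment-class].
#' @export
writeCatalogs <- function(catalogs, path) {
  df <- cbind(as.data.frame(colData(catalogs))[
                c("clone_id", "genotype", "treatment")],
              as.data.frame(t(assay(catalogs, "contexts")),
                            check.names = FALSE))
  writeTsv(df, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cohort tables

#' Read / write a patient cohort table
#'
#' Required columns: \code{patient_id} (unique), \code{rad18_expression},
#' \code{proliferation_score}, \code{signature11_count} (>= 0), and either a
#' binary \code{mgmt_status} ("low"/"high") or a real
#' \code{mgmt_expression}; an optional logical \code{hypermutation} and an
#' optional logical \code{pole_mutated} (excluded upstream of modelling) are
#' kept. Which MGMT form was provided is recorded in the
#' \code{"mgmt_form"} attribute.
#'
#' @param path file path.
#' @return data.frame with attribute \code{mgmt_form} ("status" or
#'   "expression").
#' @export
readCohort <- function(path) {
  df <- readTsv(path)
  requireColumns(df, c("patient_id", "rad18_expression",
                       "proliferation_score", "signature11_count"),
                 basename(path))
  if (anyDuplicated(df$patient_id))
    stopf("%s: duplicate patient_id", basename(path))
  if (any(df$signature11_count < 0))
    stopf("%s: signature11_count must be >= 0", basename(path))
  form <- if ("mgmt_status" %in% names(df)) "status" else
    if ("mgmt_expression" %in% names(df)) "expression" else
      stopf("%s: need mgmt_status or mgmt_expression", basename(path))
  if (form == "status" && !all(df$mgmt_status %in% c("low", "high")))
    stopf("%s: mgmt_status must be 'low' or 'high'", basename(path))
  if ("hypermutation" %in% names(df))
    df$hypermutation <- as.logical(df$hypermutation)
  if ("pole_mutated" %in% names(df))
    df$pole_mutated <- as.logical(df$pole_mutated)
  attr(df, "mgmt_form") <- form
  df
}

#' @rdname readCohort
#' @param cohort data.frame as produced by [simulateCohort()].
#' @export
writeCohort <- function(cohort, path) {
  writeTsv(cohort, path)
  invisible(path)
}
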
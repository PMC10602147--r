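#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData assayNames
NULL

# ---------------------------------------------------------------------------
# LibraryDesign: pooled CRISPR library (targeting guides + non-targeting
# controls) with an optional gene -> pathway map.

#' LibraryDesign: a pooled sgRNA library
#'
#' Holds the guide table of a pooled CRISPR knockout library -- targeting
#' guides mapped to genes plus non-targeting control (NTC) guides -- and a
#' gene-to-pathway map (a gene may belong to several pathways).
#'
#' @slot guides \code{DataFrame} with columns \code{guide_id},
#'   \code{gene_id} (\code{NA} for NTC guides) and \code{is_ntc}.
#' @slot pathways named \code{list}: \code{gene_id} -> character vector of
#'   pathway names (possibly empty).
#'
#' @seealso [makeLibraryDesign()]
#' @export
setClass("LibraryDesign",
         representation(guides = "DataFrame", pathways = "list"))

setValidity("LibraryDesign", function(object) {
  g <- object@guides
  req <- c("guide_id", "gene_id", "is_ntc")
  if (!all(req %in% colnames(g)))
    return(paste("guides must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(g$guide_id))
    return("guide_ids must be unique")
  if (any(g$is_ntc & !is.na(g$gene_id)))
    return("NTC guides must not carry a gene_id")
  if (any(!g$is_ntc & is.na(g$gene_id)))
    return("every targeting guide must map to exactly one gene")
  bad <- setdiff(names(object@pathways), unique(g$gene_id[!g$is_ntc]))
  if (length(bad))
    return(paste("pathway map names genes absent from the library:",
                 paste(utils::head(bad, 5), collapse = ", ")))
  TRUE
})

#' @describeIn LibraryDesign guide table (\code{DataFrame}).
#' @param design,object A \code{LibraryDesign}.
#' @export
guideTable <- function(design) design@guides

#' @describeIn LibraryDesign gene -> pathways map (named list).
#' @export
pathwayMap <- function(design) design@pathways

#' @describeIn LibraryDesign gene identifiers (targeting genes only).
#' @export
libraryGenes <- function(design)
  unique(design@guides$gene_id[!design@guides$is_ntc])

#' @describeIn LibraryDesign guide_ids of the non-targeting controls.
#' @export
ntcGuides <- function(design)
  design@guides$guide_id[design@guides$is_ntc]

setMethod("show", "LibraryDesign", function(object) {
  g <- object@guides
  cat("LibraryDesign:", sum(!g$is_ntc), "targeting guides over",
      length(libraryGenes(object)), "genes;",
      sum(g$is_ntc), "non-targeting controls\n")
  np <- length(unique(unlist(object@pathways)))
  cat("  pathway map:", np, "pathway(s) covering",
      sum(lengths(object@pathways) > 0), "gene(s)\n")
})

# ---------------------------------------------------------------------------
# ScreenExperiment: guide x sample counts with screen sample metadata.

#' ScreenExperiment: sgRNA counts from a pooled dropout screen
#'
#' A \code{SummarizedExperiment} of guide-level counts (raw in assay
#' \code{"counts"}; [normalizeCounts()] adds assay \code{"cpm"}). Rows are
#' guides (rowData: \code{gene_id}, \code{is_ntc}); columns are sequenced
#' samples (colData: \code{timepoint} PD0/PD20, \code{treatment},
#' \code{genotype}, \code{replicate}).
#'
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  cd <- colData(object)
  req <- c("timepoint", "treatment", "genotype", "replicate")
  if (!all(req %in% colnames(cd)))
    return(paste("colData must have columns", paste(req, collapse = ", ")))
  if (!all(cd$timepoint %in% c("PD0", "PD20")))
    return("timepoint must be 'PD0' or 'PD20'")
  rd <- rowData(object)
  if (!all(c("gene_id", "is_ntc") %in% colnames(rd)))
    return("rowData must have columns gene_id, is_ntc")
  if (any(assay(object, "counts") < 0))
    return("counts must be non-negative")
  TRUE
})

#' Construct a ScreenExperiment
#'
#' @param counts integer/numeric matrix, guides x samples; rownames are
#'   guide_ids, colnames are sample names.
#' @param guideInfo data.frame/DataFrame with \code{guide_id},
#'   \code{gene_id}, \code{is_ntc}, aligned with or matchable to the rows.
#' @param sampleInfo data.frame/DataFrame with \code{sample},
#'   \code{timepoint}, \code{treatment}, \code{genotype}, \code{replicate}.
#' @return A \code{ScreenExperiment}.
#' @export
ScreenExperiment <- function(counts, guideInfo, sampleInfo) {
  guideInfo <- as.data.frame(guideInfo)
  sampleInfo <- as.data.frame(sampleInfo)
  requireColumns(guideInfo, c("guide_id", "gene_id", "is_ntc"), "guideInfo")
  requireColumns(sampleInfo,
                 c("sample", "timepoint", "treatment", "genotype", "replicate"),
                 "sampleInfo")
  if (is.null(rownames(counts))) rownames(counts) <- guideInfo$guide_id
  m <- match(rownames(counts), guideInfo$guide_id)
  if (anyNA(m)) stopf("counts rows contain guide_ids absent from guideInfo")
  guideInfo <- guideInfo[m, , drop = FALSE]
  ms <- match(colnames(counts), sampleInfo$sample)
  if (anyNA(ms)) stopf("counts columns contain samples absent from sampleInfo")
  sampleInfo <- sampleInfo[ms, , drop = FALSE]
  se <- SummarizedExperiment(
    assays = SimpleList(counts = counts),
    rowData = DataFrame(guideInfo, row.names = guideInfo$guide_id),
    colData = DataFrame(sampleInfo, row.names = sampleInfo$sample))
  new("ScreenExperiment", se)
}

# ---------------------------------------------------------------------------
# CatalogExperiment: 96-context mutation catalogs, one column per clone/sample.

#' CatalogExperiment: per-clone 96-context mutation catalogs
#'
#' A \code{SummarizedExperiment} whose single assay \code{"contexts"} is the
#' 96 x n matrix of trinucleotide-context SNV counts (rows in
#' [contextLabels96()] order); colData carries \code{clone_id},
#' \code{genotype} and \code{treatment} arm labels.
#'
#' @export
setClass("CatalogExperiment", contains = "SummarizedExperiment")

setValidity("CatalogExperiment", function(object) {
  if (!"contexts" %in% assayNames(object))
    return("assay 'contexts' is required")
  m <- assay(object, "contexts")
  if (nrow(m) != 96L) return("context matrix must have 96 rows")
  if (!identical(rownames(m), contextLabels96()))
    return("context rows must be the canonical 96 labels, in order")
  if (any(m < 0)) return("context counts must be non-negative")
  cd <- colData(object)
  req <- c("clone_id", "genotype", "treatment")
  if (!all(req %in% colnames(cd)))
    return(paste("colData must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(cd$clone_id)) return("clone_ids must be unique")
  TRUE
})

#' Construct a CatalogExperiment
#'
#' @param contexts 96 x n numeric matrix of context counts, rownames in
#'   [contextLabels96()] order (set automatically when absent).
#' @param cloneInfo data.frame with \code{clone_id}, \code{genotype},
#'   \code{treatment}, one row per column of \code{contexts}.
#' @return A \code{CatalogExperiment}.
#' @export
CatalogExperiment <- function(contexts, cloneInfo) {
  cloneInfo <- as.data.frame(cloneInfo)
  requireColumns(cloneInfo, c("clone_id", "genotype", "treatment"),
                 "cloneInfo")
  if (is.null(rownames(contexts))) rownames(contexts) <- contextLabels96()
  colnames(contexts) <- cloneInfo$clone_id
  se <- SummarizedExperiment(
    assays = SimpleList(contexts = contexts),
    colData = DataFrame(cloneInfo, row.names = cloneInfo$clone_id))
  new("CatalogExperiment", se)
}

#' @describeIn CatalogExperiment 6 x n matrix of substitution-class counts
#'   (C>A, C>G, C>T, T>A, T>C, T>G), each class the sum of its 16 context
#'   bins.
#' @param x A \code{CatalogExperiment}.
#' @export
classCounts <- function(x) {
  m <- assay(x, "contexts")
  cls <- sub("^.\\[(.>.)\\].$", "\\1", rownames(m))
  rowsum(m, cls)[SUBSTITUTION_CLASSES, , drop = FALSE]
}

#' @describeIn CatalogExperiment total SNV count per clone (named vector).
#' @export
totalSNV <- function(x) colSums(assay(x, "contexts"))

# ---------------------------------------------------------------------------
# SignatureSet: a fixed 96 x K mutational-signature probability matrix.

#' SignatureSet: reference mutational signatures
#'
#' A 96 x K matrix of trinucleotide-context probabilities, one column per
#' signature; every column is non-negative and sums to 1.
#'
#' @slot probs numeric 96 x K matrix; rownames are [contextLabels96()],
#'   colnames are signature names (e.g. \code{"Signature 11"}).
#' @export
setClass("SignatureSet", representation(probs = "matrix"))

setValidity("SignatureSet", function(object) {
  p <- object@probs
  if (nrow(p) != 96L) return("expected 96 context rows")
  if (!identical(rownames(p), contextLabels96()))
    return("rows must be the canonical 96 context labels, in order")
  if (is.null(colnames(p)) || anyDuplicated(colnames(p)))
    return("signature names must be present and unique")
  if (any(p < 0)) return("signature probabilities must be non-negative")
  cs <- colSums(p)
  if (any(abs(cs - 1) > 1e-6))
    return("every signature column must sum to 1 (tolerance 1e-6)")
  TRUE
})

#' Construct a SignatureSet
#'
#' Columns whose sums lie within 1e-3 of 1 are renormalized; larger
#' discrepancies are rejected.
#'
#' @param probs numeric 96 x K matrix with signature columns.
#' @return A \code{SignatureSet}.
#' @export
SignatureSet <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 96L)
    stopf("expected 96 context rows, got %d", nrow(probs))
  if (is.null(rownames(probs))) rownames(probs) <- contextLabels96()
  if (!identical(rownames(probs), contextLabels96())) {
    if (!setequal(rownames(probs), contextLabels96()))
      stopf("context row labels do not match the canonical 96 labels")
    probs <- probs[contextLabels96(), , drop = FALSE]
  }
  if (any(probs < 0)) stopf("signature probabilities must be non-negative")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-3))
    stopf("signature column(s) %s do not sum to 1 (off by more than 1e-3)",
          paste(colnames(probs)[abs(cs - 1) > 1e-3], collapse = ", "))
  probs <- sweep(probs, 2, cs, "/")
  new("SignatureSet", probs = probs)
}

#' @describeIn SignatureSet the 96 x K probability matrix.
#' @param x,object A \code{SignatureSet}.
#' @export
signatureProbs <- function(x) x@probs

#' @describeIn SignatureSet signature names.
#' @export
signatureNames <- function(x) colnames(x@probs)

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet:", ncol(object@probs), "signature(s) x 96 contexts\n")
  cat("  names:", paste(utils::head(signatureNames(object), 8),
                        collapse = ", "),
      if (ncol(object@probs) > 8) "...\n" else "\n")
})

# ---------------------------------------------------------------------------
# SignatureExposure: NNLS refit of one catalog against a SignatureSet.

#' SignatureExposure: signature attribution for one catalog
#'
#' Result of [nnlsFit()]: non-negative per-signature mutation counts, the
#' reconstruction and the residual norm.
#'
#' @slot sampleId character(1).
#' @slot exposures named non-negative numeric, mutation counts per signature.
#' @slot reconstruction numeric(96), \code{probs \%*\% exposures}.
#' @slot residualNorm numeric(1), \eqn{\|S a - m\|_2}.
#' @export
setClass("SignatureExposure",
         representation(sampleId = "character", exposures = "numeric",
                        reconstruction = "numeric", residualNorm = "numeric"))

#' @describeIn SignatureExposure named exposure vector (mutation counts).
#' @param x,object A \code{SignatureExposure}.
#' @export
exposures <- function(x) x@exposures

#' @describeIn SignatureExposure L2 norm of the reconstruction residual.
#' @export
residualNorm <- function(x) x@residualNorm

setMethod("show", "SignatureExposure", function(object) {
  cat("SignatureExposure for", object@sampleId, "\n")
  nz <- object@exposures[object@exposures > 1e-8]
  cat("  nonzero exposures:",
      paste(sprintf("%s=%.1f", names(nz), nz), collapse = ", "), "\n")
  cat("  residual norm:", format(object@residualNorm, digits = 4), "\n")
})

# ---------------------------------------------------------------------------
# HypermutationFit: logistic model of hypermutation on adjusted expression.

#' HypermutationFit: logistic association model
#'
#' Coefficients, Wald statistics and convergence state of the logistic model
#' \code{hypermutation ~ rad18_adj + mgmt} fitted by [fitHypermutationModel()].
#'
#' @slot coefficients numeric matrix with columns estimate, std_error,
#'   z_value, p_value; one row per model term.
#' @slot converged logical(1).
#' @slot nIter integer(1), IRLS iterations used.
#' @slot n integer(1), number of patients fitted.
#' @export
setClass("HypermutationFit",
         representation(coefficients = "matrix", converged = "logical",
                        nIter = "integer", n = "integer"))

#' @describeIn HypermutationFit coefficient table (estimate, std_error,
#'   z_value, p_value).
#' @param object A \code{HypermutationFit}.
#' @export
setMethod("coef", "HypermutationFit", function(object) object@coefficients)

setMethod("show", "HypermutationFit", function(object) {
  cat("HypermutationFit on", object@n, "patients;",
      if (object@converged) "converged" else "NOT converged",
      "in", object@nIter, "IRLS iterations\n")
  print(round(object@coefficients, 4))
})
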
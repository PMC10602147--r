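# Synthetic-data generators: every downstream stage can be exercised with
# known ground truth, no external downloads.

DEFAULT_PATHWAYS <- c("BER", "TLS", "FA", "HR", "NHEJ",
                      "NER", "CS", "MASC", "PARP", "NM")

#' Build a pooled DDR-style CRISPR library design
#'
#' Default dimensions follow the screened DDR library: 504 genes x 10 guides
#' (5040 targeting sgRNAs) plus 1000 non-targeting controls. Pathway
#' membership defaults to a deterministic round-robin assignment over ten DDR
#' pathway labels; pass \code{pathwaySpec} to control it (a gene may belong
#' to several pathways).
#'
#' @param nGenes number of targeted genes (default 504).
#' @param guidesPerGene guides per gene (default 10).
#' @param nNTC number of non-targeting control guides (default 1000).
#' @param pathwaySpec named list \code{pathway -> character vector of
#'   gene_ids}, or \code{NULL} for the default round-robin assignment over
#'   \code{DEFAULT_PATHWAYS}.
#' @param seed integer seed (the default design is deterministic; the seed is
#'   accepted so callers can treat all generators uniformly).
#' @return A [LibraryDesign-class].
#' @examples
#' d <- makeLibraryDesign(6, 2, 3)
#' guideTable(d)
#' @export
makeLibraryDesign <- function(nGenes = 504L, guidesPerGene = 10L,
                              nNTC = 1000L, pathwaySpec = NULL, seed = 1L) {
  if (nGenes < 0 || guidesPerGene < 0 || nNTC < 0)
    stopf("library sizes must be non-negative")
  genes <- if (nGenes > 0) sprintf("GENE%04d", seq_len(nGenes)) else character(0)
  tg <- if (nGenes > 0 && guidesPerGene > 0) data.frame(
    guide_id = paste0(rep(genes, each = guidesPerGene), "_g",
                      sprintf("%02d", seq_len(guidesPerGene))),
    gene_id = rep(genes, each = guidesPerGene),
    is_ntc = FALSE) else
    data.frame(guide_id = character(0), gene_id = character(0),
               is_ntc = logical(0))
  ntc <- if (nNTC > 0) data.frame(
    guide_id = sprintf("NTC_%04d", seq_len(nNTC)),
    gene_id = NA_character_, is_ntc = TRUE) else
    data.frame(guide_id = character(0), gene_id = character(0),
               is_ntc = logical(0))
  guides <- rbind(tg, ntc)
  if (is.null(pathwaySpec)) {
    pmap <- as.list(DEFAULT_PATHWAYS[(seq_along(genes) - 1L) %%
                                       length(DEFAULT_PATHWAYS) + 1L])
    names(pmap) <- genes
  } else {
    pmap <- stats::setNames(vector("list", length(genes)), genes)
    for (pw in names(pathwaySpec)) {
      gs <- intersect(pathwaySpec[[pw]], genes)
      for (g in gs) pmap[[g]] <- c(pmap[[g]], pw)
    }
    pmap <- pmap[!vapply(pmap, is.null, logical(1))]
  }
  new("LibraryDesign",
      guides = DataFrame(guides, row.names = guides$guide_id),
      pathways = pmap)
}

#' Simulate a pooled dropout screen
#'
#' Counts are negative-binomial around an expected abundance of
#' \code{baselineMean} per guide at PD0. The PD20 expectation of a guide is
#' its PD0 expectation times \code{2^(effect * doublings)}; by default the
#' PD20 expectations are then rescaled to the PD0 library size, mimicking
#' sequencing at fixed read depth (dropout is relative). Non-targeting
#' guides always have effect 0. One PD0 and one PD20 sample are produced per
#' (treatment, replicate).
#'
#' @param design A [LibraryDesign-class].
#' @param baselineMean expected PD0 count per guide (> 0).
#' @param dispersion negative-binomial overdispersion \eqn{\phi} in
#'   \eqn{Var = \mu + \phi \mu^2}; 0 gives Poisson counts.
#' @param geneEffects \code{NULL} (all effects 0) or a data.frame with
#'   columns \code{gene_id}, \code{treatment}, \code{effect} (true per-
#'   doubling log2 fitness effect).
#' @param nReplicates independent screens (default 3).
#' @param doublings population doublings between PD0 and PD20 (default 20).
#' @param treatments character vector of treatment arms.
#' @param genotype genotype label stored in colData.
#' @param renormalizeDepth rescale PD20 expectations to the PD0 library size
#'   before sampling (default \code{TRUE}).
#' @param seed integer seed; identical seeds give identical counts.
#' @return A [ScreenExperiment-class].
#' @export
simulateScreen <- function(design, baselineMean = 500, dispersion = 0.3,
                           geneEffects = NULL, nReplicates = 3L,
                           doublings = 20L,
                           treatments = c("DMSO", "TMZ"),
                           genotype = "WT", renormalizeDepth = TRUE,
                           seed = 1L) {
  stopifnot(baselineMean > 0, dispersion >= 0, nReplicates >= 1)
  g <- as.data.frame(guideTable(design))
  nG <- nrow(g)
  if (nG == 0L) stopf("design contains no guides")
  rnb <- function(mu) {
    if (dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  effectFor <- function(trt) {
    eff <- numeric(nG)
    if (!is.null(geneEffects)) {
      requireColumns(geneEffects, c("gene_id", "treatment", "effect"),
                     "geneEffects")
      ge <- geneEffects[geneEffects$treatment == trt, , drop = FALSE]
      m <- match(g$gene_id, ge$gene_id)
      eff[!is.na(m)] <- ge$effect[m[!is.na(m)]]
    }
    eff[g$is_ntc] <- 0
    eff
  }
  withSeed(seed, {
    cols <- list(); info <- list()
    for (trt in treatments) {
      mu20raw <- baselineMean * 2^(effectFor(trt) * doublings)
      mu20 <- if (renormalizeDepth)
        mu20raw * (nG * baselineMean) / sum(mu20raw) else mu20raw
      for (r in seq_len(nReplicates)) {
        for (tp in c("PD0", "PD20")) {
          mu <- if (tp == "PD0") rep(baselineMean, nG) else mu20
          nm <- paste(genotype, trt, tp, paste0("r", r), sep = "_")
          cols[[nm]] <- rnb(mu)
          info[[nm]] <- data.frame(sample = nm, timepoint = tp,
                                   treatment = trt, genotype = genotype,
                                   replicate = r)
        }
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- g$guide_id
    ScreenExperiment(counts, g, do.call(rbind, info))
  })
}

#' Deterministic synthetic signature panel
#'
#' A small, fully synthetic stand-in for a reference signature matrix in the
#' COSMIC v2 layout (96 pyrimidine-centred contexts x signatures). It is NOT
#' the COSMIC catalogue: columns are constructed to caricature familiar
#' processes so that refitting is testable offline -- "Signature 1"
#' (deamination-like C>T at CpG), "Signature 3" (flat), "Signature 4"
#' (C>A-dominated), "Signature 5" (T>C-leaning), "Signature 11"
#' (alkylation-like C>T away from CpG, the temozolomide-associated pattern)
#' and "Signature 17" (T>G at TT).
#'
#' @return A [SignatureSet-class] with 6 signatures.
#' @export
syntheticSignatures <- function() {
  labs <- contextLabels96()
  f5 <- substr(labs, 1, 1)
  cls <- sub("^.\\[(.>.)\\].$", "\\1", labs)
  f3 <- substr(labs, 7, 7)
  w <- function(weights) weights / sum(weights)
  sig1 <- w(ifelse(cls == "C>T" & f3 == "G", 20,
                   ifelse(cls == "C>T", 0.5, 0.1)))
  sig3 <- w(rep(1, 96))
  sig4 <- w(ifelse(cls == "C>A", 10, ifelse(cls == "T>A", 1, 0.2)))
  sig5 <- w(ifelse(cls == "T>C", 8, ifelse(cls == "C>T", 2, 0.5)))
  sig11 <- w(ifelse(cls == "C>T" & f3 != "G",
                    ifelse(f5 %in% c("C", "T"), 25, 10),
                    ifelse(cls == "C>T", 1, 0.05)))
  sig17 <- w(ifelse(cls == "T>G" & f5 == "T", 30, 0.2))
  probs <- cbind("Signature 1" = sig1, "Signature 3" = sig3,
                 "Signature 4" = sig4, "Signature 5" = sig5,
                 "Signature 11" = sig11, "Signature 17" = sig17)
  rownames(probs) <- labs
  SignatureSet(probs)
}

# vectorized: variant fields for mutations in contexts `label`; records with
# flip = TRUE are written on the purine strand
contextToVariant <- function(label, flip) {
  ref <- substr(label, 3, 3)
  alt <- substr(label, 5, 5)
  ctx <- paste0(substr(label, 1, 1), ref, substr(label, 7, 7))
  if (any(flip)) {
    ctx[flip] <- revComp(ctx[flip])
    ref[flip] <- revComp(ref[flip])
    alt[flip] <- revComp(alt[flip])
  }
  list(ref = ref, alt = alt, context = ctx)
}

#' Simulate per-clone mutation catalogs and variant records
#'
#' Each arm (genotype x treatment) contributes \code{nClones} clones (default
#' 6, matching a six-clones-per-condition design). A clone's total SNV count
#' is Poisson around the summed signature activities of its arm, and contexts
#' are multinomial over the activity-weighted signature mixture. Per-variant
#' records (MAF, tumor/normal depths, supporting reads, trinucleotide
#' context) are emitted alongside the ground-truth catalogs so the filtering
#' stage is exercised; about half the records are written on the purine
#' strand to exercise pyrimidine-strand folding. Optionally,
#' \code{artifactsPerClone} artifact records per clone are added that each
#' violate one filter rule (low MAF, low coverage, few supporting reads,
#' known polymorphism, off-exome, or a long indel); these are excluded from
#' the ground truth.
#'
#' @param arms data.frame with columns \code{genotype}, \code{treatment} and
#'   optionally \code{n_clones} (default 6).
#' @param signatures A [SignatureSet-class].
#' @param activities matrix (signatures x arms) or named list
#'   \code{"genotype.treatment" -> numeric(K)} of non-negative expected
#'   mutation counts per signature; a plain numeric vector is recycled to
#'   every arm.
#' @param artifactsPerClone artifact records per clone (default 0).
#' @param seed integer seed.
#' @return list with \code{variants} (data.frame of variant records, incl.
#'   \code{clone_id}), \code{catalogs} (ground-truth
#'   [CatalogExperiment-class]) and \code{activities} (the matrix used).
#' @export
simulateCatalogs <- function(arms, signatures = syntheticSignatures(),
                             activities, artifactsPerClone = 0L, seed = 1L) {
  arms <- as.data.frame(arms)
  requireColumns(arms, c("genotype", "treatment"), "arms")
  if (is.null(arms$n_clones)) arms$n_clones <- 6L
  S <- signatureProbs(signatures)
  K <- ncol(S)
  armKey <- paste(arms$genotype, arms$treatment, sep = ".")
  if (is.list(activities)) {
    activities <- vapply(armKey, function(k) {
      a <- activities[[k]]
      if (is.null(a)) stopf("no activities supplied for arm %s", k)
      a
    }, numeric(K))
  } else if (is.null(dim(activities))) {
    activities <- matrix(rep(activities, length(armKey)), nrow = K,
                         dimnames = list(colnames(S), armKey))
  }
  activities <- as.matrix(activities)
  if (nrow(activities) != K || ncol(activities) != nrow(arms))
    stopf("activities must be %d signatures x %d arms", K, nrow(arms))
  if (any(activities < 0)) stopf("activities must be non-negative")
  colnames(activities) <- armKey
  rownames(activities) <- colnames(S)
  labs <- contextLabels96()

  withSeed(seed, {
    cloneRows <- list(); varRows <- list(); ctxCols <- list()
    cloneN <- 0L
    for (i in seq_len(nrow(arms))) {
      act <- activities[, i]
      lambda <- sum(act)
      p <- if (lambda > 0) as.vector(S %*% act) / lambda else rep(0, 96)
      for (k in seq_len(arms$n_clones[i])) {
        cloneN <- cloneN + 1L
        cid <- sprintf("clone_%03d", cloneN)
        total <- if (lambda > 0) stats::rpois(1, lambda) else 0L
        ctx <- if (total > 0)
          as.vector(stats::rmultinom(1, total, p)) else integer(96)
        ctxCols[[cid]] <- ctx
        cloneRows[[cid]] <- data.frame(clone_id = cid,
                                       genotype = arms$genotype[i],
                                       treatment = arms$treatment[i])
        mkVar <- function(label) {
          n <- length(label)
          if (n == 0L) return(NULL)
          v <- contextToVariant(label, stats::runif(n) < 0.5)
          data.frame(clone_id = cid, chrom = "chr1",
                     pos = 0L,  # assigned after assembly (unique, sorted)
                     ref = v$ref, alt = v$alt,
                     variant_type = "SNV",
                     maf = round(stats::runif(n, 0.15, 0.9), 3),
                     depth_tumor = stats::rpois(n, 80) + 10L,
                     depth_normal = stats::rpois(n, 80) + 10L,
                     alt_reads = 0L, context = v$context,
                     known_polymorphism = FALSE,
                     in_exome_interval = TRUE)
        }
        vr <- mkVar(rep(labs, ctx))
        if (!is.null(vr))
          vr$alt_reads <- pmax(3L, stats::rbinom(nrow(vr), vr$depth_tumor,
                                                 vr$maf))
        if (artifactsPerClone > 0) {
          af <- mkVar(sample(labs, artifactsPerClone, replace = TRUE))
          af$alt_reads <- pmax(3L, stats::rbinom(nrow(af), af$depth_tumor,
                                                 af$maf))
          kind <- sample(c("maf", "depth", "altreads", "poly", "exome",
                           "indel"), artifactsPerClone, replace = TRUE)
          for (j in seq_len(artifactsPerClone)) {
            switch(kind[j],
              maf = { af$maf[j] <- 0.05 },
              depth = { af$depth_tumor[j] <- 5L },
              altreads = { af$alt_reads[j] <- 2L },
              poly = { af$known_polymorphism[j] <- TRUE },
              exome = { af$in_exome_interval[j] <- FALSE },
              indel = {
                af$variant_type[j] <- "deletion"
                af$ref[j] <- paste(rep("A", 12), collapse = "")
                af$alt[j] <- "A"
                af$context[j] <- "AAA"
              })
          }
          vr <- rbind(vr, af)
        }
        if (!is.null(vr)) varRows[[cid]] <- vr
      }
    }
    variants <- if (length(varRows)) do.call(rbind, varRows) else
      data.frame()
    if (nrow(variants) > 0) {
      variants$pos <- seq_len(nrow(variants)) * 100L
      rownames(variants) <- NULL
    }
    ctxMat <- do.call(cbind, ctxCols)
    rownames(ctxMat) <- labs
    list(variants = variants,
         catalogs = CatalogExperiment(ctxMat, do.call(rbind, cloneRows)),
         activities = activities)
  })
}

#' Simulate a patient cohort for the hypermutation model
#'
#' Expression is linear in the proliferation score plus Gaussian noise; the
#' hypermutation label is Bernoulli under the logistic model
#' \eqn{logit(p) = \beta_0 + \beta_{RAD18} \epsilon + \beta_{MGMT} mgmt}
#' on the noise residual \eqn{\epsilon} (the quantity proliferation
#' adjustment recovers) and a binary MGMT status. Signature-11 counts are
#' drawn consistently with the label around the calling threshold.
#'
#' @param nPatients cohort size (>= 10).
#' @param beta0,betaRad18,betaMgmt logistic coefficients of the generating
#'   model.
#' @param intercept,slope linear model of expression on proliferation.
#' @param noiseSd residual SD of expression (> 0).
#' @param threshold Signature-11 hypermutation threshold (default 500).
#' @param seed integer seed.
#' @return data.frame with patient_id, rad18_expression,
#'   proliferation_score, mgmt_status ("low"/"high"), signature11_count and
#'   hypermutation (logical).
#' @export
simulateCohort <- function(nPatients = 200L, beta0 = -1, betaRad18 = -0.8,
                           betaMgmt = -0.5, intercept = 5, slope = 2,
                           noiseSd = 1, threshold = 500, seed = 1L) {
  if (nPatients < 10) stopf("nPatients must be >= 10")
  if (noiseSd <= 0) stopf("noiseSd must be > 0")
  withSeed(seed, {
    prolif <- stats::rnorm(nPatients)
    eps <- stats::rnorm(nPatients, 0, noiseSd)
    expr <- intercept + slope * prolif + eps
    mgmt <- stats::rbinom(nPatients, 1, 0.5)
    eta <- beta0 + betaRad18 * eps + betaMgmt * mgmt
    hyper <- stats::rbinom(nPatients, 1, stats::plogis(eta)) == 1L
    sig11 <- ifelse(hyper,
                    threshold * (1 + stats::rexp(nPatients)),
                    stats::runif(nPatients, 0, 0.9 * threshold))
    data.frame(patient_id = sprintf("PT%05d", seq_len(nPatients)),
               rad18_expression = expr,
               proliferation_score = prolif,
               mgmt_status = ifelse(mgmt == 1L, "high", "low"),
               signature11_count = sig11,
               hypermutation = hyper)
  })
}
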
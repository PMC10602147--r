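# Signature refitting: non-negative least squares of a 96-context catalog
# against a fixed signature matrix, Signature-11 extraction and the
# hypermutation call.

# Lawson-Hanson active-set non-negative least squares:
# minimize ||A x - b||_2 subject to x >= 0. The problem is convex with a
# unique optimum whenever the active columns are independent; convergence is
# certified by the KKT conditions (gradient w = A'(b - Ax): w <= tol on the
# zero set, |w| <= tol on the positive set).
nnlsSolve <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(1, sqrt(sum(b^2))) * max(1, norm(A, "F"))
  x <- numeric(n)
  P <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0L; maxIter <- 30L * n
  while (any(!P) && max(w[!P]) > tol && iter < maxIter) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[P][is.na(s[P])] <- 0
      if (all(s[P] > tol * 1e-4)) { x <- s; break }
      inner <- P & (s <= tol * 1e-4)
      alpha <- min(x[inner] / (x[inner] - s[inner]))
      x <- x + alpha * (s - x)
      P[P & (x <= tol * 1e-4)] <- FALSE
      x[!P] <- 0
      if (!any(P)) { x <- numeric(n); break }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Refit a catalog against fixed signatures (NNLS)
#'
#' Finds the non-negative exposure vector \eqn{a} minimizing
#' \eqn{\|S a - m\|_2} for the 96-context catalog \eqn{m} -- the global
#' optimum of this convex problem, computed by the Lawson-Hanson active-set
#' algorithm and certified against the KKT conditions. Exposures are in
#' mutation counts, not proportions.
#'
#' @param catalog96 numeric vector of 96 non-negative context counts (in
#'   [contextLabels96()] order, or named by context labels).
#' @param signatures A [SignatureSet-class].
#' @param sampleId identifier stored in the result.
#' @return A [SignatureExposure-class].
#' @export
nnlsFit <- function(catalog96, signatures, sampleId = "sample") {
  S <- signatureProbs(signatures)
  m <- as.numeric(catalog96)
  if (length(m) != 96L) stopf("catalog must have 96 context counts")
  if (any(m < 0)) stopf("catalog counts must be non-negative")
  if (!is.null(names(catalog96))) {
    if (!setequal(names(catalog96), rownames(S)))
      stopf("catalog names do not match the signature contexts")
    m <- as.numeric(catalog96[rownames(S)])
  }
  a <- if (all(m == 0)) numeric(ncol(S)) else nnlsSolve(S, m)
  names(a) <- colnames(S)
  rec <- drop(S %*% a)
  new("SignatureExposure", sampleId = sampleId, exposures = a,
      reconstruction = rec,
      residualNorm = sqrt(sum((rec - m)^2)))
}

#' Refit every clone in a catalog set
#'
#' Applies [nnlsFit()] per sample (default) or to the pooled catalog of each
#' genotype x treatment group.
#'
#' @param catalogs A [CatalogExperiment-class].
#' @param signatures A [SignatureSet-class].
#' @param by \code{"sample"} (default) or \code{"group"}.
#' @return data.frame with one row per fitted unit: clone/group id, arm
#'   labels, one column per signature exposure, and residual_norm.
#' @export
fitSignatures <- function(catalogs, signatures, by = c("sample", "group")) {
  by <- match.arg(by)
  m <- assay(catalogs, "contexts")
  cd <- as.data.frame(colData(catalogs))
  if (by == "group") {
    grp <- paste(cd$genotype, cd$treatment, sep = ".")
    m <- t(rowsum(t(m), grp))
    cd <- unique(data.frame(clone_id = grp, genotype = cd$genotype,
                            treatment = cd$treatment))
    cd <- cd[match(colnames(m), cd$clone_id), ]
  }
  fits <- lapply(seq_len(ncol(m)), function(i)
    nnlsFit(m[, i], signatures, sampleId = colnames(m)[i]))
  exp <- do.call(rbind, lapply(fits, function(f) f@exposures))
  data.frame(sample_id = colnames(m),
             genotype = cd$genotype, treatment = cd$treatment,
             exp, residual_norm = vapply(fits, residualNorm, numeric(1)),
             check.names = FALSE, row.names = NULL)
}

#' Extract a named signature's mutation count
#'
#' @param exposure A [SignatureExposure-class].
#' @param name signature name (default \code{"Signature 11"}, the
#'   alkylation-associated signature used for hypermutation calling).
#' @return numeric(1) mutation count attributed to that signature.
#' @export
signature11Counts <- function(exposure, name = "Signature 11") {
  e <- exposures(exposure)
  if (!name %in% names(e))
    stopf("signature '%s' not in the fit; available: %s", name,
          paste(names(e), collapse = ", "))
  unname(e[name])
}

#' Call hypermutation from a Signature-11 count
#'
#' A sample is hypermutated when its Signature-11 mutation count strictly
#' exceeds the threshold (default 500): 500 is negative, 501 positive.
#'
#' @param count non-negative Signature-11 mutation count (vectorized).
#' @param threshold calling threshold (default 500).
#' @return data.frame with signature11_count, threshold, is_hypermutated.
#' @export
callHypermutation <- function(count, threshold = 500) {
  if (any(count < 0)) stopf("count must be non-negative")
  data.frame(signature11_count = count, threshold = threshold,
             is_hypermutated = count > threshold)
}
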
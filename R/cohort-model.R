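# Proliferation-adjusted expression, tertile stratification, and the
# logistic hypermutation association model.

#' Proliferation-adjusted RAD18 expression
#'
#' Regresses expression on the proliferation score by ordinary least squares
#' (\code{lm(rad18_expression ~ proliferation_score)}) and takes the
#' residual as adjusted expression, removing the contribution of highly
#' proliferative samples. Rows flagged \code{pole_mutated} are excluded
#' before any computation (with a message). Adds tertile group labels and,
#' when absent, the hypermutation label from the Signature-11 threshold.
#'
#' @param cohort data.frame as returned by [readCohort()] /
#'   [simulateCohort()].
#' @param threshold Signature-11 hypermutation threshold (default 500),
#'   used only when \code{cohort$hypermutation} is absent.
#' @return the cohort with added columns \code{rad18_adj} (residual),
#'   \code{rad18_group} (low/medium/high) and \code{hypermutation}.
#' @export
adjustExpression <- function(cohort, threshold = 500) {
  if ("pole_mutated" %in% names(cohort) && any(cohort$pole_mutated)) {
    message(sprintf("excluding %d POLE-mutated sample(s)",
                    sum(cohort$pole_mutated)))
    cohort <- cohort[!cohort$pole_mutated, , drop = FALSE]
  }
  if (nrow(cohort) < 3) stopf("need >= 3 patients")
  if (stats::sd(cohort$proliferation_score) == 0)
    stopf("proliferation score is constant; slope unidentifiable")
  fit <- stats::lm(rad18_expression ~ proliferation_score, data = cohort)
  cohort$rad18_adj <- unname(stats::residuals(fit))
  cohort$rad18_group <- stratifyTertiles(cohort$rad18_adj)
  if (!"hypermutation" %in% names(cohort))
    cohort$hypermutation <- cohort$signature11_count > threshold
  cohort
}

#' Tertile stratification
#'
#' Rank-based split into \code{"low"}, \code{"medium"} and \code{"high"}
#' groups of sizes as equal as possible; when n is not divisible by 3 the
#' extra member(s) go to the lower group(s) (n = 10 gives 4/3/3). Ties are
#' broken by stable input order, so labels are invariant to monotone
#' transforms of the values.
#'
#' @param values numeric vector (length >= 3).
#' @return factor with levels low < medium < high, aligned with the input.
#' @export
stratifyTertiles <- function(values) {
  n <- length(values)
  if (n < 3) stopf("need >= 3 values to form tertiles")
  sizes <- rep(n %/% 3L, 3L)
  rem <- n %% 3L
  if (rem >= 1L) sizes[1] <- sizes[1] + 1L
  if (rem == 2L) sizes[2] <- sizes[2] + 1L
  lab <- rep(c("low", "medium", "high"), times = sizes)
  out <- character(n)
  out[order(values)] <- lab  # order() is stable: ties keep input order
  factor(out, levels = c("low", "medium", "high"))
}

# single-covariate complete-separation check: TRUE when the covariate
# perfectly orders the two outcome classes
separates <- function(x, y) {
  max(x[!y]) < min(x[y]) || max(x[y]) < min(x[!y])
}

#' Logistic hypermutation association model
#'
#' Fits \code{hypermutation ~ rad18_adj + mgmt} by maximum likelihood
#' (binomial GLM with logit link, iteratively reweighted least squares) and
#' reports Wald z statistics and two-sided p-values per coefficient. MGMT
#' enters as provided: a binary status column (\code{"low"}/\code{"high"},
#' coded high = 1) or a continuous \code{mgmt_expression} column. Errors on
#' a single-class outcome or on perfect separation (naming the separating
#' covariate).
#'
#' @param cohort data.frame from [adjustExpression()] (needs
#'   \code{rad18_adj}, \code{hypermutation} and an MGMT column).
#' @return A [HypermutationFit-class].
#' @export
fitHypermutationModel <- function(cohort) {
  requireColumns(cohort, c("rad18_adj", "hypermutation"), "cohort")
  y <- as.logical(cohort$hypermutation)
  if (length(unique(y)) < 2L)
    stopf("outcome has a single class; the model is not estimable")
  mgmt <- if ("mgmt_status" %in% names(cohort)) {
    as.numeric(cohort$mgmt_status == "high")
  } else if ("mgmt_expression" %in% names(cohort)) {
    cohort$mgmt_expression
  } else stopf("cohort needs mgmt_status or mgmt_expression")
  for (nm in c("rad18_adj", "mgmt")) {
    x <- if (nm == "mgmt") mgmt else cohort[[nm]]
    if (stats::sd(x) > 0 && separates(x, y))
      stopf("perfect separation on covariate '%s'; coefficients diverge", nm)
  }
  df <- data.frame(y = y, rad18_adj = cohort$rad18_adj, mgmt = mgmt)
  fit <- suppressWarnings(
    stats::glm(y ~ rad18_adj + mgmt, family = stats::binomial("logit"),
               data = df, control = stats::glm.control(epsilon = 1e-10,
                                                       maxit = 100)))
  cf <- summary(fit)$coefficients
  colnames(cf) <- c("estimate", "std_error", "z_value", "p_value")
  new("HypermutationFit", coefficients = cf,
      converged = fit$converged, nIter = as.integer(fit$iter),
      n = nrow(df))
}
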
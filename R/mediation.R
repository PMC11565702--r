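# Two-step MR mediation: product of coefficients, delta-method CIs,
# FDR screening of candidate mediators.

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment: after sorting ascending,
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in input
#' order (delegates to [stats::p.adjust()] after validating the input).
#'
#' @param pvals vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bhFDR <- function(pvals) {
  if (!length(pvals))
    .mrStop("config_error", "bhFDR needs a non-empty p-value vector")
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    .mrStop("config_error", "p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Two-step mediation decomposition
#'
#' Product-of-coefficients decomposition of a total effect TE (exposure to
#' outcome) into the indirect path through one mediator and the direct
#' remainder: IE = beta1 * beta2, DE = TE - IE, mediated proportion IE/TE.
#' Uncertainty is first-order delta method with the three estimates treated
#' as independent (they come from non-overlapping two-sample analyses):
#' se(IE)^2 = beta2^2 se1^2 + beta1^2 se2^2 and
#' se(prop)^2 = se(IE)^2/TE^2 + IE^2 se(TE)^2/TE^4, with 95% normal CIs.
#'
#' @param te [MREstimate-class] (or number) for the exposure-outcome total
#'   effect, on the log-OR (or linear) scale.
#' @param b1 [MREstimate-class] (or number) for the exposure-mediator
#'   effect.
#' @param b2 [MREstimate-class] (or number) for the mediator-outcome
#'   effect.
#' @param teSe,b1Se,b2Se standard errors, required when the corresponding
#'   estimate is given as a bare number.
#' @param mediatorId label carried into the result.
#' @return A [MediationResult-class]. When TE = 0 the proportion is
#'   undefined: a classed warning (`mrchain_undefined_proportion`) fires
#'   and the proportion fields are `NA` while IE and DE are still returned.
#' @examples
#' m <- twoStepMediation(te = log(1.092), teSe = 0.0206,
#'                       b1 = log(0.982), b1Se = 0.0070,
#'                       b2 = log(0.885), b2Se = 0.0598)
#' mediatedProportion(m)  # about 0.025
#' @export
twoStepMediation <- function(te, b1, b2, teSe = NULL, b1Se = NULL,
                             b2Se = NULL, mediatorId = "mediator") {
  pick <- function(x, se, what) {
    if (is(x, "MREstimate")) return(c(x@beta, x@se))
    if (is.null(se))
      .mrStop("config_error", "%s given as a number needs its SE", what)
    c(as.numeric(x), as.numeric(se))
  }
  teV <- pick(te, teSe, "te"); b1V <- pick(b1, b1Se, "b1")
  b2V <- pick(b2, b2Se, "b2")
  ie <- b1V[1L] * b2V[1L]
  ieSe <- sqrt(b2V[1L]^2 * b1V[2L]^2 + b1V[1L]^2 * b2V[2L]^2)
  de <- teV[1L] - ie
  z <- .zcrit()
  if (teV[1L] == 0) {
    .mrWarn("undefined_proportion",
            "total effect is zero; mediated proportion undefined")
    prop <- propSe <- pLow <- pHigh <- NA_real_
  } else {
    prop <- ie / teV[1L]
    propSe <- sqrt(ieSe^2 / teV[1L]^2 + ie^2 * teV[2L]^2 / teV[1L]^4)
    pLow <- prop - z * propSe
    pHigh <- prop + z * propSe
  }
  new("MediationResult", mediatorId = mediatorId,
      te = teV[1L], teSe = teV[2L], beta1 = b1V[1L], beta1Se = b1V[2L],
      beta2 = b2V[1L], beta2Se = b2V[2L], ie = ie, ieSe = ieSe,
      ieCiLow = ie - z * ieSe, ieCiHigh = ie + z * ieSe, de = de,
      proportion = prop, propSe = propSe, propCiLow = pLow,
      propCiHigh = pHigh)
}

# univariable MR of a pre-selected instrument set against a target dataset;
# returns an MREstimate (IVW auto; Wald-ratio fallback at 1 SNP) or NULL
.instrumentedEffect <- function(instruments, target, dropPalindromic,
                                palindromicEafWindow) {
  h <- tryCatch(harmonize(instruments, target,
                          dropPalindromic = dropPalindromic,
                          palindromicEafWindow = palindromicEafWindow),
                mrchain_empty_overlap = function(e) NULL)
  if (is.null(h)) return(NULL)
  if (length(h) >= 2L) return(mrIVW(h, "auto"))
  waldRatio(h@betaExp, h@seExp, h@betaOut, h@seOut)
}

#' Screen candidate mediators by two-step MR with FDR control
#'
#' Step 1 estimates the exposure's effect on every candidate mediator using
#' the exposure's instruments and adjusts the p-values by Benjamini-
#' Hochberg across the whole panel; mediators with q < `alpha` proceed.
#' Step 2 estimates each surviving mediator's effect on the outcome using
#' the mediator's own instruments (selected with `cfg`); survivors at
#' unadjusted p < `alpha` receive a full mediation decomposition against
#' the supplied (or internally computed, univariable) total effect.
#'
#' @param exposure a [SummaryStats-class]; its instruments are selected
#'   with `cfg`.
#' @param mediators list of [SummaryStats-class] candidate mediators.
#' @param outcome a [SummaryStats-class].
#' @param ld an [LdInfo-class].
#' @param cfg an [InstrumentConfig-class].
#' @param alpha step-1 q-value and step-2 p-value threshold (default 0.05).
#' @param te optional [MREstimate-class] total effect; computed as the
#'   heterogeneity-gated IVW of exposure on outcome when `NULL`.
#' @param dropPalindromic,palindromicEafWindow harmonization policy.
#' @return data.frame with one row per mediator: step-1 estimate/p/q,
#'   step-2 estimate/p, IE, DE, mediated proportion with CI, and a
#'   `status` column in `fail_step1`, `fail_step2`, `no_instruments`,
#'   `mediator`. The full [MediationResult-class] objects for rows with
#'   status `mediator` are attached as `attr(x, "results")`.
#' @export
screenMediators <- function(exposure, mediators, outcome,
                            ld = ldIndependent(), cfg = instrumentConfig(),
                            alpha = 0.05, te = NULL, dropPalindromic = TRUE,
                            palindromicEafWindow = 0.08) {
  stopifnot(is.list(mediators), length(mediators) >= 1L)
  ids <- vapply(mediators, traitId, character(1L))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  exInstr <- selectInstruments(exposure, ld, cfg)
  if (is.null(te)) {
    h <- harmonize(exInstr, outcome, dropPalindromic, palindromicEafWindow)
    te <- mrIVW(h, "auto")
  }
  m <- length(mediators)
  step1 <- lapply(mediators, .instrumentedEffect, instruments = exInstr,
                  dropPalindromic = dropPalindromic,
                  palindromicEafWindow = palindromicEafWindow)
  grab <- function(lst, fn) vapply(lst, function(e)
    if (is.null(e)) NA_real_ else fn(e), numeric(1L))
  out <- data.frame(
    mediator_id = ids,
    step1_beta = grab(step1, estimate), step1_se = grab(step1, stdError),
    step1_nsnps = grab(step1, nSnps), step1_pval = grab(step1, pValue),
    step1_q = NA_real_, step2_beta = NA_real_, step2_se = NA_real_,
    step2_nsnps = NA_real_, step2_pval = NA_real_, ie = NA_real_,
    ie_se = NA_real_, de = NA_real_, proportion = NA_real_,
    prop_se = NA_real_, prop_ci_low = NA_real_, prop_ci_high = NA_real_,
    status = NA_character_, stringsAsFactors = FALSE)
  est1 <- !is.na(out$step1_pval)
  out$status[!est1] <- "no_instruments"
  if (any(est1)) out$step1_q[est1] <- bhFDR(out$step1_pval[est1])
  proceed <- est1 & out$step1_q < alpha
  out$status[est1 & !proceed[est1]] <- "fail_step1"
  results <- list()
  for (i in which(proceed)) {
    medInstr <- tryCatch(selectInstruments(mediators[[i]], ld, cfg),
                         mrchain_no_instruments = function(e) NULL)
    s2 <- if (is.null(medInstr)) NULL else
      .instrumentedEffect(medInstr, outcome, dropPalindromic,
                          palindromicEafWindow)
    if (is.null(s2)) {
      out$status[i] <- "no_instruments"
      next
    }
    out$step2_beta[i] <- s2@beta
    out$step2_se[i] <- s2@se
    out$step2_nsnps[i] <- s2@nSnps
    out$step2_pval[i] <- s2@pval
    if (s2@pval >= alpha) {
      out$status[i] <- "fail_step2"
      next
    }
    med <- twoStepMediation(te, out$step1_beta[i], s2,
                            b1Se = out$step1_se[i], mediatorId = ids[i])
    out$ie[i] <- med@ie; out$ie_se[i] <- med@ieSe; out$de[i] <- med@de
    out$proportion[i] <- med@proportion; out$prop_se[i] <- med@propSe
    out$prop_ci_low[i] <- med@propCiLow
    out$prop_ci_high[i] <- med@propCiHigh
    out$status[i] <- "mediator"
    results[[ids[i]]] <- med
  }
  attr(out, "results") <- results
  attr(out, "te") <- te
  out
}
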
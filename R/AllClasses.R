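#' @import methods
NULL

# canonical column order of the summary-statistics exchange format
.SUMSTAT_COLUMNS <- c("variant_id", "chromosome", "position", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pval", "n")

.ALLELE_RE <- "^[ACGT]+$"

#' GWAS summary statistics for one trait
#'
#' Per-variant effect estimates from a single genome-wide association study,
#' the raw material of every two-sample MR analysis. Each record carries the
#' variant identifier, location, effect/other alleles, effect-allele
#' frequency, the per-allele effect size (a log odds ratio for binary
#' traits), its standard error, the association p-value and the per-variant
#' sample size.
#'
#' @slot traitId character(1). Dataset identifier (e.g. a GWAS accession).
#' @slot traitLabel character(1). Human-readable trait name.
#' @slot sampleSize numeric(1). Study sample size, `NA` when unknown.
#' @slot records data.frame with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`.
#' @slot meta list. Provenance: input path, invalid-row tally, stage counts.
#'
#' @examples
#' ss <- SummaryStats(
#'   data.frame(variant_id = "rs1", chromosome = "1", position = 1000L,
#'              effect_allele = "A", other_allele = "G", eaf = 0.3,
#'              beta = 0.1, se = 0.01, pval = 1e-20, n = 10000L),
#'   traitId = "example")
#' nVariants(ss)
#' @export
setClass("SummaryStats",
  representation(traitId = "character", traitLabel = "character",
                 sampleSize = "numeric", records = "data.frame",
                 meta = "list"))

.validSummaryStats <- function(object) {
  r <- object@records
  msgs <- character()
  missing <- setdiff(.SUMSTAT_COLUMNS, names(r))
  if (length(missing))
    return(sprintf("records missing columns: %s", paste(missing, collapse = ", ")))
  if (anyDuplicated(r$variant_id))
    msgs <- c(msgs, "variant_id values must be unique within a dataset")
  if (nrow(r)) {
    if (any(is.na(r$se)) || any(r$se <= 0))
      msgs <- c(msgs, "all se must be positive")
    if (any(is.na(r$pval)) || any(r$pval <= 0 | r$pval > 1))
      msgs <- c(msgs, "all pval must lie in (0, 1]")
    if (any(r$effect_allele == r$other_allele))
      msgs <- c(msgs, "effect_allele must differ from other_allele")
    if (any(!grepl(.ALLELE_RE, r$effect_allele)) ||
        any(!grepl(.ALLELE_RE, r$other_allele)))
      msgs <- c(msgs, "alleles must be strings over {A,C,G,T}")
    bad_eaf <- !is.na(r$eaf) & (r$eaf < 0 | r$eaf > 1)
    if (any(bad_eaf)) msgs <- c(msgs, "eaf must lie in [0, 1] when present")
    if (any(!is.na(r$position) & r$position < 0))
      msgs <- c(msgs, "position must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("SummaryStats", .validSummaryStats)

#' Construct a SummaryStats object
#'
#' @param records data.frame of per-variant associations; missing optional
#'   columns (`chromosome`, `position`, `eaf`, `n`) are filled with `NA`.
#' @param traitId,traitLabel dataset identifier and label.
#' @param sampleSize study sample size (`NA` if unknown).
#' @param meta provenance list.
#' @return A validated [SummaryStats-class] object.
#' @export
SummaryStats <- function(records, traitId = "trait", traitLabel = traitId,
                         sampleSize = NA_real_, meta = list()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("chromosome", "position", "eaf", "n")) {
    if (is.null(records[[col]])) {
      records[[col]] <- if (col == "chromosome") NA_character_ else NA_real_
    }
  }
  records$variant_id <- as.character(records$variant_id)
  records$chromosome <- as.character(records$chromosome)
  records$position <- as.numeric(records$position)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    records[[col]] <- as.numeric(records[[col]])
  records <- records[, .SUMSTAT_COLUMNS, drop = FALSE]
  rownames(records) <- NULL
  new("SummaryStats", traitId = traitId, traitLabel = traitLabel,
      sampleSize = as.numeric(sampleSize), records = records, meta = meta)
}

#' Exposure-outcome effects aligned to a shared effect-allele frame
#'
#' The substrate of every MR estimator: per-variant exposure and outcome
#' effects expressed for the same effect allele, with every removed variant
#' recorded in a drop log together with its reason.
#'
#' @slot variantIds character. Retained variant identifiers.
#' @slot betaExp,seExp numeric. SNP-exposure effects and standard errors.
#' @slot betaOut,seOut numeric. SNP-outcome effects and standard errors.
#' @slot exposureId,outcomeId character(1). Source dataset identifiers.
#' @slot dropLog data.frame with columns `variant_id`, `reason`.
#' @export
setClass("HarmonizedSet",
  representation(variantIds = "character", betaExp = "numeric",
                 seExp = "numeric", betaOut = "numeric", seOut = "numeric",
                 exposureId = "character", outcomeId = "character",
                 dropLog = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  n <- length(object@variantIds)
  msgs <- character()
  if (n < 1) msgs <- c(msgs, "at least one retained variant is required")
  lens <- c(length(object@betaExp), length(object@seExp),
            length(object@betaOut), length(object@seOut))
  if (any(lens != n)) msgs <- c(msgs, "all effect vectors must share one length")
  if (any(object@seExp <= 0) || any(object@seOut <= 0))
    msgs <- c(msgs, "standard errors must be positive")
  if (!all(c("variant_id", "reason") %in% names(object@dropLog)))
    msgs <- c(msgs, "dropLog needs variant_id and reason columns")
  else if (any(object@variantIds %in% object@dropLog$variant_id))
    msgs <- c(msgs, "a variant cannot be both retained and dropped")
  if (anyDuplicated(object@variantIds))
    msgs <- c(msgs, "retained variant ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a HarmonizedSet
#'
#' Usually produced by [harmonize()]; the constructor is exported for
#' simulation and testing where effects are already on a common frame.
#'
#' @param variantIds retained variant identifiers.
#' @param betaExp,seExp,betaOut,seOut aligned effect and SE vectors.
#' @param exposureId,outcomeId dataset identifiers.
#' @param dropLog data.frame(variant_id, reason) of removed variants.
#' @return A validated [HarmonizedSet-class].
#' @export
HarmonizedSet <- function(variantIds, betaExp, seExp, betaOut, seOut,
                          exposureId = "exposure", outcomeId = "outcome",
                          dropLog = data.frame(variant_id = character(),
                                               reason = character())) {
  new("HarmonizedSet", variantIds = as.character(variantIds),
      betaExp = as.numeric(betaExp), seExp = as.numeric(seExp),
      betaOut = as.numeric(betaOut), seOut = as.numeric(seOut),
      exposureId = exposureId, outcomeId = outcomeId,
      dropLog = as.data.frame(dropLog, stringsAsFactors = FALSE))
}

#' A causal-effect estimate from one MR method
#'
#' Effect sizes are kept on the log odds-ratio scale internally; odds ratios
#' appear only at the reporting boundary via [oddsRatio()] and
#' `as.data.frame()`.
#'
#' @slot method character(1). One of `wald_ratio`, `ivw_fe`, `ivw_re`,
#'   `egger`, `weighted_median`, `weighted_mode`.
#' @slot beta,se numeric(1). Estimate (log-OR) and standard error.
#' @slot ciLow,ciHigh numeric(1). 95% confidence bounds.
#' @slot pval numeric(1). Two-sided normal-theory p-value.
#' @slot nSnps integer(1). Instruments used.
#' @slot extra list. Method-specific detail (e.g. Egger intercept, the
#'   IVW model chosen by the heterogeneity gate).
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 nSnps = "integer", extra = "list"))

setValidity("MREstimate", function(object) {
  msgs <- character()
  if (!(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    msgs <- c(msgs, "confidence interval must bracket the estimate")
  if (is.na(object@se) || object@se <= 0)
    msgs <- c(msgs, "se must be positive")
  if (object@pval <= 0 || object@pval > 1)
    msgs <- c(msgs, "pval must lie in (0, 1]")
  if (object@nSnps < 1L) msgs <- c(msgs, "nSnps must be >= 1")
  if (length(msgs)) msgs else TRUE
})

.mrEstimate <- function(method, beta, se, nSnps, extra = list(), level = 0.95) {
  z <- .zcrit(level)
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - z * se, ciHigh = beta + z * se,
      pval = .zp(beta, se), nSnps = as.integer(nSnps), extra = extra)
}

#' Heterogeneity test result (Cochran's Q)
#'
#' @slot Q numeric(1). Heterogeneity statistic over per-variant ratios.
#' @slot df integer(1). Degrees of freedom, instruments minus one.
#' @slot pval numeric(1). Upper-tail chi-square p-value.
#' @export
setClass("HeterogeneityResult",
  representation(Q = "numeric", df = "integer", pval = "numeric"))

setValidity("HeterogeneityResult", function(object) {
  msgs <- character()
  if (object@Q < 0) msgs <- c(msgs, "Q must be non-negative")
  if (object@pval <= 0 || object@pval > 1) msgs <- c(msgs, "pval must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Directional-pleiotropy test result (Egger intercept)
#'
#' @slot intercept,interceptSe numeric(1). Egger regression intercept and SE.
#' @slot pval numeric(1). Two-sided normal test of intercept / SE.
#' @export
setClass("PleiotropyResult",
  representation(intercept = "numeric", interceptSe = "numeric",
                 pval = "numeric"))

setValidity("PleiotropyResult", function(object) {
  msgs <- character()
  if (object@interceptSe <= 0) msgs <- c(msgs, "interceptSe must be positive")
  expect <- .zp(object@intercept, object@interceptSe)
  if (abs(object@pval - expect) > 1e-8)
    msgs <- c(msgs, "pval inconsistent with normal test of intercept/interceptSe")
  if (length(msgs)) msgs else TRUE
})

#' MR-PRESSO result: global, outlier and distortion tests
#'
#' @slot globalRss numeric(1). Observed leave-one-out residual sum of squares.
#' @slot globalPval numeric(1). Simulation p-value of the global test.
#' @slot outlierIndices integer. Positions (in input order) of flagged SNPs.
#' @slot outlierPvals numeric. Bonferroni-adjusted per-SNP outlier p-values.
#' @slot distortionPval numeric(1). Distortion-test p, `NA` without outliers.
#' @slot estimateRaw MREstimate on all instruments.
#' @slot estimateCorrected MREstimate on non-outliers, or `NULL`.
#' @slot nSim,seed integer(1). Simulation size and RNG seed.
#' @export
setClass("PressoResult",
  representation(globalRss = "numeric", globalPval = "numeric",
                 outlierIndices = "integer", outlierPvals = "numeric",
                 distortionPval = "numeric", estimateRaw = "MREstimate",
                 estimateCorrected = "ANY", nSim = "integer",
                 seed = "integer"))

setValidity("PressoResult", function(object) {
  msgs <- character()
  if (object@globalRss < 0) msgs <- c(msgs, "globalRss must be non-negative")
  if (object@globalPval <= 0 || object@globalPval > 1)
    msgs <- c(msgs, "globalPval must lie in (0, 1]")
  n <- length(object@outlierPvals)
  if (length(object@outlierIndices) &&
      (min(object@outlierIndices) < 1L || max(object@outlierIndices) > n))
    msgs <- c(msgs, "outlier indices must index the instrument set")
  if (length(msgs)) msgs else TRUE
})

#' Multi-exposure instrument set for multivariable MR
#'
#' @slot variantIds character. Retained variants.
#' @slot betaExp,seExp matrix. n_snps x k exposure effects and SEs.
#' @slot betaOut,seOut numeric. Outcome effects and SEs.
#' @slot exposureIds character. Column identifiers (k >= 2).
#' @slot outcomeId character(1).
#' @slot dropLog data.frame(variant_id, reason).
#' @export
setClass("MvmrDataset",
  representation(variantIds = "character", betaExp = "matrix",
                 seExp = "matrix", betaOut = "numeric", seOut = "numeric",
                 exposureIds = "character", outcomeId = "character",
                 dropLog = "data.frame"))

setValidity("MvmrDataset", function(object) {
  n <- length(object@variantIds)
  k <- length(object@exposureIds)
  msgs <- character()
  if (k < 1) msgs <- c(msgs, "at least one exposure column is required")
  if (!all(dim(object@betaExp) == c(n, k)) || !all(dim(object@seExp) == c(n, k)))
    msgs <- c(msgs, "exposure matrices must be n_snps x k")
  if (length(object@betaOut) != n || length(object@seOut) != n)
    msgs <- c(msgs, "outcome vectors must match variant count")
  if (n <= k) msgs <- c(msgs, "model is under-identified: n_snps must exceed k")
  if (n && (any(object@seExp <= 0) || any(object@seOut <= 0)))
    msgs <- c(msgs, "standard errors must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Multivariable MR estimates (one row per exposure)
#'
#' @slot table data.frame with per-exposure beta, se, ci, pval and OR columns.
#' @slot nSnps integer(1). Instruments in the joint model.
#' @slot exposureIds character. Conditioning set.
#' @export
setClass("MvmrEstimate",
  representation(table = "data.frame", nSnps = "integer",
                 exposureIds = "character"))

setValidity("MvmrEstimate", function(object) {
  tb <- object@table
  msgs <- character()
  need <- c("exposure", "beta", "se", "ci_low", "ci_high", "pval",
            "odds_ratio", "or_ci_low", "or_ci_high")
  if (!all(need %in% names(tb)))
    return("table is missing per-exposure estimate columns")
  if (nrow(tb) != length(object@exposureIds))
    msgs <- c(msgs, "one table row per exposure is required")
  if (nrow(tb) && any(!(tb$ci_low <= tb$beta & tb$beta <= tb$ci_high)))
    msgs <- c(msgs, "confidence intervals must bracket the estimates")
  if (length(msgs)) msgs else TRUE
})

#' Two-step mediation decomposition for one mediator
#'
#' Total effect TE (exposure to outcome), beta1 (exposure to mediator),
#' beta2 (mediator to outcome), indirect effect IE = beta1 x beta2 with a
#' first-order delta-method SE, direct effect DE = TE - IE, and the mediated
#' proportion IE / TE with a ratio delta-method SE.
#'
#' @slot mediatorId character(1).
#' @slot te,teSe,beta1,beta1Se,beta2,beta2Se numeric(1). Input estimates.
#' @slot ie,ieSe,ieCiLow,ieCiHigh numeric(1). Indirect effect and 95% CI.
#' @slot de numeric(1). Direct effect.
#' @slot proportion,propSe,propCiLow,propCiHigh numeric(1). Mediated
#'   proportion with delta-method uncertainty (`NA` when TE = 0).
#' @export
setClass("MediationResult",
  representation(mediatorId = "character", te = "numeric", teSe = "numeric",
                 beta1 = "numeric", beta1Se = "numeric", beta2 = "numeric",
                 beta2Se = "numeric", ie = "numeric", ieSe = "numeric",
                 ieCiLow = "numeric", ieCiHigh = "numeric", de = "numeric",
                 proportion = "numeric", propSe = "numeric",
                 propCiLow = "numeric", propCiHigh = "numeric"))

setValidity("MediationResult", function(object) {
  msgs <- character()
  if (abs(object@ie - object@beta1 * object@beta2) > 1e-12 * max(1, abs(object@ie)))
    msgs <- c(msgs, "IE must equal beta1 * beta2")
  if (abs((object@de + object@ie) - object@te) > 1e-12 * max(1, abs(object@te)))
    msgs <- c(msgs, "DE + IE must equal TE")
  if (length(msgs)) msgs else TRUE
})

#' Linkage-disequilibrium information for clumping
#'
#' Either a declared "independent" mode asserting all candidate variants are
#' unlinked, or a pairwise r-squared lookup (symmetric; absent pairs are
#' treated according to the clumping policy).
#'
#' @slot mode character(1). `"independent"` or `"pairs"`.
#' @slot pairs data.frame with columns `variant_a`, `variant_b`, `r2`.
#' @export
setClass("LdInfo",
  representation(mode = "character", pairs = "data.frame"))

setValidity("LdInfo", function(object) {
  msgs <- character()
  if (!object@mode %in% c("independent", "pairs"))
    msgs <- c(msgs, "mode must be 'independent' or 'pairs'")
  if (object@mode == "pairs") {
    p <- object@pairs
    if (!all(c("variant_a", "variant_b", "r2") %in% names(p)))
      msgs <- c(msgs, "pairs needs variant_a, variant_b, r2 columns")
    else if (nrow(p) && (any(p$r2 < 0) || any(p$r2 > 1)))
      msgs <- c(msgs, "r2 values must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Instrument-selection thresholds
#'
#' Defaults follow standard two-sample MR practice: genome-wide significance
#' p < 5e-8, clumping window 10,000 kb with r-squared <= 0.001, and
#' instrument strength F > 10.
#'
#' @slot pThreshold numeric(1). Significance threshold (strict `<`).
#' @slot clumpKb numeric(1). Physical window in kilobases.
#' @slot clumpR2 numeric(1). Maximum tolerated r-squared with an index SNP.
#' @slot fMin numeric(1). Minimum F-statistic (strict `>`).
#' @export
setClass("InstrumentConfig",
  representation(pThreshold = "numeric", clumpKb = "numeric",
                 clumpR2 = "numeric", fMin = "numeric"))

setValidity("InstrumentConfig", function(object) {
  msgs <- character()
  if (object@pThreshold <= 0 || object@pThreshold >= 1)
    msgs <- c(msgs, "pThreshold must lie in (0, 1)")
  if (object@clumpR2 < 0 || object@clumpR2 > 1)
    msgs <- c(msgs, "clumpR2 must lie in [0, 1]")
  if (object@clumpKb < 0) msgs <- c(msgs, "clumpKb must be >= 0")
  if (object@fMin < 0) msgs <- c(msgs, "fMin must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @param pThreshold,clumpKb,clumpR2,fMin see slot documentation.
#' @return A validated [InstrumentConfig-class].
#' @rdname InstrumentConfig-class
#' @export
instrumentConfig <- function(pThreshold = 5e-8, clumpKb = 10000,
                             clumpR2 = 0.001, fMin = 10) {
  new("InstrumentConfig", pThreshold = pThreshold, clumpKb = clumpKb,
      clumpR2 = clumpR2, fMin = fMin)
}

#' Full result bundle of one pipeline run
#'
#' @slot estimates data.frame. One row per estimator (OR-scale reporting).
#' @slot diagnostics list. Heterogeneity, pleiotropy, MR-PRESSO,
#'   leave-one-out and funnel blocks.
#' @slot mvmr `MvmrEstimate` or `NULL`.
#' @slot mediation data.frame of screen rows, or `NULL`.
#' @slot stageCounts data.frame. Instrument attrition per stage.
#' @slot provenance list. Config echo, hash, seeds, package version.
#' @slot flags character. Raised analysis flags (e.g. `pleiotropy`).
#' @slot status character(1). `completed` or `completed-with-flags`.
#' @export
setClass("AnalysisReport",
  representation(estimates = "data.frame", diagnostics = "list",
                 mvmr = "ANY", mediation = "ANY",
                 stageCounts = "data.frame", provenance = "list",
                 flags = "character", status = "character"))
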
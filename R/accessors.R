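# Accessor and show methods for the core classes.

#' @rdname mrchain-accessors
setMethod("traitId", "SummaryStats", function(x) x@traitId)

#' @rdname mrchain-accessors
setMethod("traitLabel", "SummaryStats", function(x) x@traitLabel)

#' @rdname mrchain-accessors
setMethod("records", "SummaryStats", function(x) x@records)

#' @rdname mrchain-accessors
setMethod("nVariants", "SummaryStats", function(x) nrow(x@records))

#' @rdname mrchain-accessors
setMethod("nVariants", "HarmonizedSet", function(x) length(x@variantIds))

#' @rdname mrchain-accessors
setMethod("variantIds", "HarmonizedSet", function(x) x@variantIds)

#' @rdname mrchain-accessors
setMethod("variantIds", "MvmrDataset", function(x) x@variantIds)

#' @rdname mrchain-accessors
setMethod("betaExp", "HarmonizedSet", function(x) x@betaExp)

#' @rdname mrchain-accessors
setMethod("seExp", "HarmonizedSet", function(x) x@seExp)

#' @rdname mrchain-accessors
setMethod("betaOut", "HarmonizedSet", function(x) x@betaOut)

#' @rdname mrchain-accessors
setMethod("seOut", "HarmonizedSet", function(x) x@seOut)

#' @rdname mrchain-accessors
setMethod("betaExp", "MvmrDataset", function(x) x@betaExp)

#' @rdname mrchain-accessors
setMethod("seExp", "MvmrDataset", function(x) x@seExp)

#' @rdname mrchain-accessors
setMethod("betaOut", "MvmrDataset", function(x) x@betaOut)

#' @rdname mrchain-accessors
setMethod("seOut", "MvmrDataset", function(x) x@seOut)

#' @rdname mrchain-accessors
setMethod("dropLog", "HarmonizedSet", function(x) x@dropLog)

#' @rdname mrchain-accessors
setMethod("dropLog", "MvmrDataset", function(x) x@dropLog)

#' Subset a HarmonizedSet by variant index
#'
#' @param x a [HarmonizedSet-class].
#' @param i integer or logical index over retained variants.
#' @param j,drop,... ignored.
#' @return A [HarmonizedSet-class] with the selected variants; the drop log
#'   is carried over unchanged.
#' @export
setMethod("[", "HarmonizedSet", function(x, i, j, ..., drop = FALSE) {
  HarmonizedSet(x@variantIds[i], x@betaExp[i], x@seExp[i],
                x@betaOut[i], x@seOut[i], x@exposureId, x@outcomeId,
                x@dropLog)
})

#' @rdname mrchain-accessors
#' @export
setMethod("length", "HarmonizedSet", function(x) length(x@variantIds))

#' @rdname mrchain-accessors
setMethod("estimate", "MREstimate", function(x) x@beta)

#' @rdname mrchain-accessors
setMethod("stdError", "MREstimate", function(x) x@se)

#' @rdname mrchain-accessors
setMethod("pValue", "MREstimate", function(x) x@pval)

#' @rdname mrchain-accessors
setMethod("confInt", "MREstimate", function(x) c(x@ciLow, x@ciHigh))

#' @rdname mrchain-accessors
setMethod("oddsRatio", "MREstimate", function(x) exp(x@beta))

#' @rdname mrchain-accessors
setMethod("nSnps", "MREstimate", function(x) x@nSnps)

#' @rdname mrchain-accessors
setMethod("mrMethod", "MREstimate", function(x) x@method)

#' @rdname mrchain-accessors
setMethod("mrExtra", "MREstimate", function(x) x@extra)

#' @rdname mrchain-accessors
setMethod("pValue", "HeterogeneityResult", function(x) x@pval)

#' @rdname mrchain-accessors
setMethod("pValue", "PleiotropyResult", function(x) x@pval)

#' @rdname mrchain-accessors
setMethod("pValue", "PressoResult", function(x) x@globalPval)

#' @rdname mrchain-accessors
setMethod("outlierIndices", "PressoResult", function(x) x@outlierIndices)

#' @rdname mrchain-accessors
setMethod("mediatedProportion", "MediationResult", function(x) x@proportion)

#' Reporting row for an MR estimate
#'
#' @param x an [MREstimate-class].
#' @param row.names,optional,... ignored.
#' @return data.frame with method, n_snps, beta, se, CI, p and OR columns.
#' @export
setMethod("as.data.frame", "MREstimate",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(method = x@method, n_snps = x@nSnps, beta = x@beta,
               se = x@se, ci_low = x@ciLow, ci_high = x@ciHigh,
               pval = x@pval, odds_ratio = exp(x@beta),
               or_ci_low = exp(x@ciLow), or_ci_high = exp(x@ciHigh),
               stringsAsFactors = FALSE)
  })

#' @rdname mrchain-accessors
#' @export
setMethod("as.data.frame", "MvmrEstimate",
  function(x, row.names = NULL, optional = FALSE, ...) x@table)

#' @rdname mrchain-accessors
#' @export
setMethod("as.data.frame", "MediationResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(mediator_id = x@mediatorId, te = x@te, te_se = x@teSe,
               beta1 = x@beta1, beta1_se = x@beta1Se,
               beta2 = x@beta2, beta2_se = x@beta2Se,
               ie = x@ie, ie_se = x@ieSe,
               ie_ci_low = x@ieCiLow, ie_ci_high = x@ieCiHigh,
               de = x@de, proportion = x@proportion, prop_se = x@propSe,
               prop_ci_low = x@propCiLow, prop_ci_high = x@propCiHigh,
               stringsAsFactors = FALSE)
  })

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats '%s' (%s): %d variants, sample size %s\n",
              object@traitId, object@traitLabel, nrow(object@records),
              ifelse(is.na(object@sampleSize), "unknown",
                     format(object@sampleSize, big.mark = ","))))
  if (nrow(object@records)) {
    print(utils::head(object@records, 3))
    if (nrow(object@records) > 3) cat("...\n")
  }
  invisible(object)
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet %s -> %s: %d variants retained, %d dropped\n",
              object@exposureId, object@outcomeId,
              length(object@variantIds), nrow(object@dropLog)))
  invisible(object)
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s] %d SNPs\n", object@method, object@nSnps))
  cat(sprintf("  beta = %.4f (se %.4f), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              object@beta, object@se, exp(object@beta), exp(object@ciLow),
              exp(object@ciHigh), object@pval))
  invisible(object)
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q = %.4f on %d df, p = %.3g\n",
              object@Q, object@df, object@pval))
  invisible(object)
})

setMethod("show", "PleiotropyResult", function(object) {
  cat(sprintf("Egger intercept = %.5f (se %.5f), p = %.3g\n",
              object@intercept, object@interceptSe, object@pval))
  invisible(object)
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: global RSS = %.4f, global p = %.3g (%d sims)\n",
              object@globalRss, object@globalPval, object@nSim))
  if (length(object@outlierIndices)) {
    cat(sprintf("  outliers at positions: %s; distortion p = %.3g\n",
                paste(object@outlierIndices, collapse = ", "),
                object@distortionPval))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(object)
})

setMethod("show", "MvmrDataset", function(object) {
  cat(sprintf("MvmrDataset: %d variants x %d exposures (%s) -> %s\n",
              length(object@variantIds), length(object@exposureIds),
              paste(object@exposureIds, collapse = ", "), object@outcomeId))
  invisible(object)
})

setMethod("show", "MvmrEstimate", function(object) {
  cat(sprintf("Multivariable MR on %d SNPs:\n", object@nSnps))
  print(object@table)
  invisible(object)
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("Mediation through '%s':\n", object@mediatorId))
  cat(sprintf("  TE = %.4f, IE = beta1*beta2 = %.5f (se %.5f), DE = %.4f\n",
              object@te, object@ie, object@ieSe, object@de))
  if (is.na(object@proportion)) {
    cat("  mediated proportion undefined (TE = 0)\n")
  } else {
    cat(sprintf("  mediated proportion = %.2f%% (95%% CI %.2f%% to %.2f%%)\n",
                100 * object@proportion, 100 * object@propCiLow,
                100 * object@propCiHigh))
  }
  invisible(object)
})

setMethod("show", "LdInfo", function(object) {
  if (object@mode == "independent") {
    cat("LdInfo: all variants declared independent\n")
  } else {
    cat(sprintf("LdInfo: %d pairwise r2 entries\n", nrow(object@pairs)))
  }
  invisible(object)
})

setMethod("show", "InstrumentConfig", function(object) {
  cat(sprintf("InstrumentConfig: p < %g, clump %g kb / r2 <= %g, F > %g\n",
              object@pThreshold, object@clumpKb, object@clumpR2, object@fMin))
  invisible(object)
})

setMethod("show", "AnalysisReport", function(object) {
  cat(sprintf("AnalysisReport [%s]\n", object@status))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  cat(sprintf("  %d estimator rows; MVMR: %s; mediation rows: %s\n",
              nrow(object@estimates),
              if (is.null(object@mvmr)) "no" else "yes",
              if (is.null(object@mediation)) "none"
              else nrow(object@mediation)))
  invisible(object)
})
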
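# Heterogeneity, pleiotropy, leave-one-out and funnel diagnostics.

#' Cochran's Q heterogeneity test
#'
#' Q = sum_j w_j (ratio_j - theta)^2 over the per-SNP Wald ratios, where
#' theta is the fixed-effects IVW pooled estimate and w_j the first-order
#' inverse ratio variance betaExp_j^2 / seOut_j^2; chi-square on n - 1
#' degrees of freedom under homogeneity.
#'
#' @param h a [HarmonizedSet-class] with at least 2 instruments.
#' @return A [HeterogeneityResult-class].
#' @export
cochranQ <- function(h) {
  .checkH(h, 2L, "Cochran's Q")
  rt <- .ratios(h)
  theta <- sum(rt$w * rt$ratio) / sum(rt$w)
  Q <- sum(rt$w * (rt$ratio - theta)^2)
  df <- length(h) - 1L
  new("HeterogeneityResult", Q = Q, df = df,
      pval = .pclamp(stats::pchisq(Q, df, lower.tail = FALSE)))
}

#' Egger-intercept test for directional pleiotropy
#'
#' Extracts the intercept of the MR-Egger regression ([mrEgger()]) with its
#' standard error and two-sided normal p-value; a non-zero intercept is
#' evidence of directional horizontal pleiotropy.
#'
#' @param h a [HarmonizedSet-class] with at least 3 instruments.
#' @return A [PleiotropyResult-class].
#' @export
pleiotropyTest <- function(h) {
  .checkH(h, 3L, "Egger-intercept test")
  fit <- .eggerFit(h)
  new("PleiotropyResult", intercept = fit$intercept,
      interceptSe = fit$interceptSe,
      pval = .zp(fit$intercept, fit$interceptSe))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the heterogeneity-gated IVW effect excluding each
#' instrument in turn, plus the all-SNP row (`excluded = "(none)"`). A row
#' is flagged when its confidence interval lies entirely on the opposite
#' side of zero from the all-SNP point estimate, i.e. excluding that SNP
#' reverses the inferred direction.
#'
#' @param h a [HarmonizedSet-class] with at least 3 instruments.
#' @return data.frame of n + 1 rows: `excluded`, `n_snps`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `model`, `flagged`.
#' @export
leaveOneOut <- function(h) {
  .checkH(h, 3L, "leave-one-out")
  n <- length(h)
  full <- mrIVW(h, "auto")
  rows <- lapply(seq_len(n), function(j) {
    est <- mrIVW(h[-j], "auto")
    data.frame(excluded = h@variantIds[j], n_snps = n - 1L,
               beta = est@beta, se = est@se, ci_low = est@ciLow,
               ci_high = est@ciHigh, pval = est@pval,
               model = est@extra$model, stringsAsFactors = FALSE)
  })
  out <- rbind(do.call(rbind, rows),
               data.frame(excluded = "(none)", n_snps = n, beta = full@beta,
                          se = full@se, ci_low = full@ciLow,
                          ci_high = full@ciHigh, pval = full@pval,
                          model = full@extra$model, stringsAsFactors = FALSE))
  sgn <- sign(full@beta)
  out$flagged <- if (sgn > 0) out$ci_high < 0
                 else if (sgn < 0) out$ci_low > 0
                 else rep(FALSE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratios against their precisions (1 / ratio SE), for
#' external plotting, together with the IVW and Egger reference-line
#' parameters.
#'
#' @param h a [HarmonizedSet-class] (any size >= 1).
#' @return list with `points` (data.frame `variant_id`, `ratio`,
#'   `precision`), `ivwBeta`, and (when n >= 3) `eggerIntercept`,
#'   `eggerSlope`.
#' @export
funnelData <- function(h) {
  stopifnot(is(h, "HarmonizedSet"))
  if (any(h@betaExp == 0))
    .mrStop("degenerate_instrument", "zero SNP-exposure effect in funnel data")
  ratio <- h@betaOut / h@betaExp
  precision <- abs(h@betaExp) / h@seOut
  points <- data.frame(variant_id = h@variantIds, ratio = ratio,
                       precision = precision, stringsAsFactors = FALSE)
  ivwBeta <- if (length(h) >= 2) mrIVW(h, "auto")@beta
             else ratio[1L]
  out <- list(points = points, ivwBeta = ivwBeta)
  if (length(h) >= 3) {
    fit <- .eggerFit(h)
    out$eggerIntercept <- fit$intercept
    out$eggerSlope <- fit$slope
  }
  out
}
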
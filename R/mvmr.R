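# Multivariable MR: joint instrument assembly and weighted least squares.

#' Assemble a multivariable MR dataset
#'
#' Candidate instruments are the union over exposures of genome-wide-
#' significant variants (p < `cfg@pThreshold` in at least one exposure),
#' jointly clumped greedily with each variant's index p-value taken as its
#' minimum across exposures. Every retained variant must carry records in
#' all exposures and the outcome; all datasets are then aligned to the
#' first exposure's effect-allele frame (sign flips for swapped alleles,
#' palindromic variants dropped under the same policy as [harmonize()]).
#' All removals are logged with reasons. A warning fires when any
#' exposure's marginal mean F-statistic over the retained set is below 10.
#'
#' @param exposures list of at least two [SummaryStats-class] objects.
#' @param outcome a [SummaryStats-class].
#' @param ld an [LdInfo-class].
#' @param cfg an [InstrumentConfig-class].
#' @param dropPalindromic,palindromicEafWindow palindrome policy, as in
#'   [harmonize()].
#' @param missingLd clumping policy for unknown same-window LD.
#' @return An [MvmrDataset-class].
#' @export
assembleMvmr <- function(exposures, outcome, ld = ldIndependent(),
                         cfg = instrumentConfig(), dropPalindromic = TRUE,
                         palindromicEafWindow = 0.08,
                         missingLd = c("linked", "error")) {
  stopifnot(is.list(exposures), is(outcome, "SummaryStats"))
  if (length(exposures) < 2L)
    .mrStop("config_error", "multivariable MR needs at least two exposures")
  k <- length(exposures)
  expIds <- vapply(exposures, traitId, character(1L))
  recs <- lapply(exposures, records)

  # union of significant variants, with min-p across exposures as index p
  sig <- do.call(rbind, lapply(recs, function(r)
    r[r$pval < cfg@pThreshold,
      c("variant_id", "chromosome", "position", "pval"), drop = FALSE]))
  if (!nrow(sig))
    .mrStop("no_instruments",
            "no variant passes p < %g in any exposure", cfg@pThreshold)
  sig <- sig[order(sig$pval), , drop = FALSE]
  cand <- sig[!duplicated(sig$variant_id), , drop = FALSE]

  kept <- .greedyClump(cand, ld, cfg@clumpKb, cfg@clumpR2, missingLd)

  dropIds <- character(); dropWhy <- character()
  note <- function(ids, why) {
    dropIds <<- c(dropIds, ids)
    dropWhy <<- c(dropWhy, rep(why, length(ids)))
  }
  for (i in seq_len(k)) {
    miss <- kept[!kept %in% recs[[i]]$variant_id]
    if (length(miss)) note(miss, sprintf("missing_in_exposure:%s", expIds[i]))
  }
  outRec <- records(outcome)
  miss <- kept[!kept %in% outRec$variant_id]
  if (length(miss)) note(miss, "missing_in_outcome")
  kept <- setdiff(kept, dropIds)

  # align to the first exposure's allele frame
  ref <- recs[[1L]][match(kept, recs[[1L]]$variant_id), , drop = FALSE]
  pal <- .isPalindromic(ref$effect_allele, ref$other_allele)
  if (any(pal) && dropPalindromic) {
    note(kept[pal], "palindromic")
    keepMask <- !pal
    kept <- kept[keepMask]; ref <- ref[keepMask, , drop = FALSE]
    pal <- pal[keepMask]
  }
  alignTo <- function(target) {
    # returns list(beta, se, ok) for `kept` in the reference frame
    t <- target[match(kept, target$variant_id), , drop = FALSE]
    aligned <- t$effect_allele == ref$effect_allele &
               t$other_allele == ref$other_allele
    swapped <- t$effect_allele == ref$other_allele &
               t$other_allele == ref$effect_allele & !aligned
    list(beta = ifelse(swapped, -t$beta, t$beta), se = t$se,
         ok = aligned | swapped)
  }
  aligns <- lapply(recs, alignTo)
  alignOut <- alignTo(outRec)
  ok <- Reduce(`&`, lapply(aligns, `[[`, "ok")) & alignOut$ok
  if (any(pal[ok])) {
    # relaxed palindrome mode: frequency-based orientation is not attempted
    # across k+1 datasets; ambiguous palindromes are dropped
    ambiguous <- pal & ok
    note(kept[ambiguous], "palindromic")
    ok <- ok & !ambiguous
  }
  if (any(!ok)) note(kept[!ok], "mismatch")
  keepMask <- ok
  kept <- kept[keepMask]
  if (length(kept) <= k)
    .mrStop("under_identified",
            "only %d instruments for %d exposures after assembly", length(kept), k)
  betaExp <- vapply(aligns, function(a) a$beta[keepMask], numeric(sum(keepMask)))
  seExp <- vapply(aligns, function(a) a$se[keepMask], numeric(sum(keepMask)))
  dimnames(betaExp) <- dimnames(seExp) <- list(kept, expIds)
  meanF <- colMeans(betaExp^2 / seExp^2)
  weak <- expIds[meanF < 10]
  if (length(weak))
    .mrWarn("weak_instruments",
            "mean marginal F below 10 for exposure(s): %s",
            paste(weak, collapse = ", "))
  new("MvmrDataset", variantIds = kept, betaExp = betaExp, seExp = seExp,
      betaOut = alignOut$beta[keepMask], seOut = alignOut$se[keepMask],
      exposureIds = expIds, outcomeId = traitId(outcome),
      dropLog = data.frame(variant_id = dropIds, reason = dropWhy,
                           stringsAsFactors = FALSE))
}

#' Multivariable IVW estimate
#'
#' Weighted least squares of the outcome effects on the exposure-effect
#' matrix without intercept, weights 1/seOut^2. Each coefficient is an
#' exposure's direct effect on the outcome conditional on the others.
#' Standard errors come from the WLS covariance (X' W X)^{-1}; with
#' `dispersion = "q"` that covariance is scaled by the multiplicative
#' overdispersion max(Q_resid / (n - k), 1). Normal-theory CIs and
#' p-values; odds ratios by exponentiation.
#'
#' @param d an [MvmrDataset-class] (n_snps > k).
#' @param dispersion `"none"` (default) or `"q"`.
#' @return An [MvmrEstimate-class].
#' @export
mvmrIVW <- function(d, dispersion = c("none", "q")) {
  stopifnot(is(d, "MvmrDataset"))
  dispersion <- match.arg(dispersion)
  X <- d@betaExp
  y <- d@betaOut
  w <- 1 / d@seOut^2
  n <- length(y); k <- ncol(X)
  Xs <- X * sqrt(w)
  qrX <- qr(Xs)
  if (qrX$rank < k) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    .mrStop("collinear_exposures",
            "exposure effect columns are collinear: %s",
            paste(dep, collapse = ", "))
  }
  A <- crossprod(Xs)
  coef <- drop(solve(A, crossprod(X, w * y)))
  covb <- solve(A)
  if (dispersion == "q") {
    resid <- y - drop(X %*% coef)
    covb <- covb * max(sum(w * resid^2) / (n - k), 1)
  }
  se <- sqrt(diag(covb))
  z <- .zcrit()
  tb <- data.frame(exposure = colnames(X), beta = unname(coef),
                   se = unname(se), ci_low = unname(coef - z * se),
                   ci_high = unname(coef + z * se),
                   pval = unname(.zp(coef, se)),
                   odds_ratio = unname(exp(coef)),
                   or_ci_low = unname(exp(coef - z * se)),
                   or_ci_high = unname(exp(coef + z * se)),
                   n_snps = n, stringsAsFactors = FALSE)
  new("MvmrEstimate", table = tb, nSnps = as.integer(n),
      exposureIds = colnames(X))
}
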
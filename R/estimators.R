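# The causal-effect estimators: Wald ratio, IVW (fixed / random / gated),
# MR-Egger, weighted median and weighted mode.
#
# All effects are carried on the log odds-ratio scale; confidence intervals
# and p-values are normal-theory at 95% throughout. Ratio (Wald) standard
# errors use the first-order approximation se_out / |beta_exp|, so ratio
# weights are beta_exp^2 / se_out^2.

.checkH <- function(h, minSnps, what) {
  stopifnot(is(h, "HarmonizedSet"))
  if (length(h) < minSnps)
    .mrStop("insufficient_instruments",
            "%s needs at least %d instruments, got %d", what, minSnps,
            length(h))
}

.ratios <- function(h) {
  if (any(h@betaExp == 0))
    .mrStop("degenerate_instrument",
            "zero SNP-exposure effect makes the Wald ratio undefined (%s)",
            paste(h@variantIds[h@betaExp == 0], collapse = ", "))
  list(ratio = h@betaOut / h@betaExp, w = h@betaExp^2 / h@seOut^2)
}

#' Wald ratio estimate from a single instrument
#'
#' beta = betaOut / betaExp with the first-order standard error
#' |seOut / betaExp|.
#'
#' @param betaExp,seExp SNP-exposure effect and SE (SE unused by the
#'   first-order ratio SE but kept for interface symmetry).
#' @param betaOut,seOut SNP-outcome effect and SE.
#' @return An [MREstimate-class] with method `wald_ratio`.
#' @export
waldRatio <- function(betaExp, seExp, betaOut, seOut) {
  if (betaExp == 0)
    .mrStop("degenerate_instrument",
            "Wald ratio undefined for zero SNP-exposure effect")
  .mrEstimate("wald_ratio", betaOut / betaExp, abs(seOut / betaExp), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Fixed effects: weighted regression of outcome on exposure effects through
#' the origin with weights 1/seOut^2, i.e.
#' beta = sum(w bx by) / sum(w bx^2), se = sum(w bx^2)^(-1/2). The random-
#' effects model inflates the fixed SE by sqrt(max(Q/(n-1), 1)) using the
#' Cochran statistic over Wald ratios (multiplicative overdispersion floored
#' at 1). With `model = "auto"` the heterogeneity test chooses: random
#' effects when its p < 0.05, fixed otherwise; the chosen branch, Q, its df
#' and p are recorded in `mrExtra()`.
#'
#' @param h a [HarmonizedSet-class] with at least 2 instruments.
#' @param model `"auto"` (heterogeneity-gated, default), `"fixed"`, or
#'   `"random"`.
#' @return An [MREstimate-class] with method `ivw_fe` or `ivw_re`.
#' @export
mrIVW <- function(h, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  .checkH(h, 2L, "IVW")
  w <- 1 / h@seOut^2
  sxx <- sum(w * h@betaExp^2)
  beta <- sum(w * h@betaExp * h@betaOut) / sxx
  seFixed <- sqrt(1 / sxx)
  het <- cochranQ(h)
  chosen <- switch(model,
    fixed = "fixed",
    random = "random",
    auto = if (het@pval < 0.05) "random" else "fixed")
  scale <- if (chosen == "random") sqrt(max(het@Q / het@df, 1)) else 1
  .mrEstimate(if (chosen == "random") "ivw_re" else "ivw_fe",
              beta, seFixed * scale, length(h),
              extra = list(model = chosen, requested = model,
                           Q = het@Q, QDf = het@df, QPval = het@pval))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept (weights 1/seOut^2), after orienting every instrument so its
#' exposure effect is non-negative (flipping both effects preserves the
#' Wald ratio). The slope is the causal estimate; the intercept, its SE and
#' normal-theory p form the directional-pleiotropy test, stored in
#' `mrExtra()` as `intercept`, `interceptSe`, `interceptPval`. Standard
#' errors use multiplicative residual dispersion floored at 1.
#'
#' @param h a [HarmonizedSet-class] with at least 3 instruments.
#' @return An [MREstimate-class] with method `egger`.
#' @export
mrEgger <- function(h) {
  .checkH(h, 3L, "MR-Egger")
  fit <- .eggerFit(h)
  .mrEstimate("egger", fit$slope, fit$slopeSe, length(h),
              extra = list(intercept = fit$intercept,
                           interceptSe = fit$interceptSe,
                           interceptPval = .zp(fit$intercept, fit$interceptSe),
                           sigma = fit$sigma))
}

.eggerFit <- function(h) {
  s <- ifelse(h@betaExp < 0, -1, 1)
  bx <- s * h@betaExp
  by <- s * h@betaOut
  w <- 1 / h@seOut^2
  X <- cbind(intercept = 1, slope = bx)
  A <- crossprod(X * sqrt(w))
  coef <- solve(A, crossprod(X, w * by))
  resid <- by - X %*% coef
  n <- length(bx)
  sigma2 <- max(sum(w * resid^2) / (n - 2L), 1)
  covb <- sigma2 * solve(A)
  list(intercept = coef[1L], slope = coef[2L],
       interceptSe = sqrt(covb[1L, 1L]), slopeSe = sqrt(covb[2L, 2L]),
       sigma = sqrt(sigma2))
}

# weighted median with the percentile construction p_j = (S_j - w_j/2) / W
.weightedMedianCore <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1L] >= 0.5) return(x[1L])
  n <- length(x)
  if (p[n] <= 0.5) return(x[n])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Orders the per-SNP Wald ratios and takes the value at standardized
#' cumulative weight 0.5 (weights are the first-order inverse variances of
#' the ratios, with linear interpolation between adjacent order statistics).
#' Consistent when instruments carrying at least half the weight are valid.
#' The standard error comes from a seeded parametric bootstrap: each
#' replicate redraws every (betaExp, betaOut) pair from its normal sampling
#' distribution and recomputes the weighted median.
#'
#' @param h a [HarmonizedSet-class] with at least 3 instruments.
#' @param nBoot bootstrap replicates (default 1000; at least 2).
#' @param seed RNG seed for the bootstrap (default 0).
#' @return An [MREstimate-class] with method `weighted_median`.
#' @export
mrWeightedMedian <- function(h, nBoot = 1000, seed = 0) {
  .checkH(h, 3L, "weighted median")
  stopifnot(nBoot >= 2)
  rt <- .ratios(h)
  est <- .weightedMedianCore(rt$ratio, rt$w)
  n <- length(h)
  boots <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      bx <- stats::rnorm(n, h@betaExp, h@seExp)
      by <- stats::rnorm(n, h@betaOut, h@seOut)
      bx[bx == 0] <- .Machine$double.eps
      .weightedMedianCore(by / bx, bx^2 / h@seOut^2)
    }, numeric(1L))
  })
  .mrEstimate("weighted_median", est, stats::sd(boots), n,
              extra = list(nBoot = nBoot, seed = seed))
}

# weighted normal-kernel density argmax over a fixed grid
.weightedModeCore <- function(ratio, w, phi, gridN = 10000L) {
  w <- w / sum(w)
  spread <- stats::mad(ratio)
  if (spread == 0) spread <- stats::sd(ratio)
  if (is.na(spread) || spread == 0) spread <- 1e-6 * max(1, abs(ratio[1L]))
  bw <- phi * 0.9 * spread * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = gridN)
  dens <- vapply(ratio, function(r) stats::dnorm(grid, r, bw), numeric(gridN))
  height <- as.numeric(dens %*% w)
  grid[which.max(height)]
}

# fast FFT version used inside the bootstrap; same kernel and bandwidth rule
.weightedModeFast <- function(ratio, w, phi) {
  w <- w / sum(w)
  spread <- stats::mad(ratio)
  if (spread == 0) spread <- stats::sd(ratio)
  if (is.na(spread) || spread == 0) spread <- 1e-6 * max(1, abs(ratio[1L]))
  bw <- phi * 0.9 * spread * length(ratio)^(-1 / 5)
  d <- suppressWarnings(stats::density(ratio, bw = bw, weights = w,
                                       n = 1024L, cut = 3))
  d$x[which.max(d$y)]
}

#' Weighted-mode estimate
#'
#' Kernel-smoothed weighted density over the per-SNP Wald ratios (normal
#' kernel; bandwidth `phi` times a median-absolute-deviation based default,
#' 0.9 * mad(ratio) * n^(-1/5)); the estimate is the density argmax on a
#' fixed 10,000-point grid spanning the ratio range plus three bandwidths.
#' Consistent when the largest group of instruments sharing one ratio value
#' is valid. SE via seeded parametric bootstrap (FFT density per replicate).
#'
#' @param h a [HarmonizedSet-class] with at least 3 instruments.
#' @param phi bandwidth multiplier (default 1).
#' @param nBoot bootstrap replicates (default 1000; at least 2).
#' @param seed RNG seed (default 0).
#' @return An [MREstimate-class] with method `weighted_mode`.
#' @export
mrWeightedMode <- function(h, phi = 1, nBoot = 1000, seed = 0) {
  .checkH(h, 3L, "weighted mode")
  stopifnot(phi > 0, nBoot >= 2)
  rt <- .ratios(h)
  est <- .weightedModeCore(rt$ratio, rt$w, phi)
  n <- length(h)
  boots <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      bx <- stats::rnorm(n, h@betaExp, h@seExp)
      by <- stats::rnorm(n, h@betaOut, h@seOut)
      bx[bx == 0] <- .Machine$double.eps
      .weightedModeFast(by / bx, bx^2 / h@seOut^2, phi)
    }, numeric(1L))
  })
  .mrEstimate("weighted_mode", est, stats::sd(boots), n,
              extra = list(phi = phi, nBoot = nBoot, seed = seed))
}

#' All univariable estimators as one reporting table
#'
#' Runs the heterogeneity-gated IVW, MR-Egger, weighted median and weighted
#' mode on one harmonized set and binds their reporting rows.
#'
#' @param h a [HarmonizedSet-class] with at least 3 instruments.
#' @param nBoot,seed,phi passed to the bootstrap estimators.
#' @return data.frame with one row per method.
#' @export
mrEstimateAll <- function(h, nBoot = 1000, seed = 0, phi = 1) {
  do.call(rbind, list(
    as.data.frame(mrIVW(h, "auto")),
    as.data.frame(mrEgger(h)),
    as.data.frame(mrWeightedMedian(h, nBoot = nBoot, seed = seed)),
    as.data.frame(mrWeightedMode(h, phi = phi, nBoot = nBoot, seed = seed))))
}
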
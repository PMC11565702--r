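# MR-PRESSO: simulation-based global, outlier and distortion tests.

# fixed-effects IVW slope excluding index j, from precomputed sums
.looSlopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO pleiotropy residual sum of squares test
#'
#' Detects and corrects horizontally pleiotropic outlier instruments.
#'
#' Global test: for each SNP j the leave-one-out fixed-effects IVW slope
#' theta_(-j) gives the observed weighted residual w_j (betaOut_j -
#' theta_(-j) betaExp_j)^2 with w_j = 1/seOut_j^2; their sum is the observed
#' RSS. `nSim` replicate datasets are drawn with betaExp*_j ~
#' N(betaExp_j, seExp_j) and betaOut*_j ~ N(theta_(-j) betaExp_j, seOut_j),
#' each processed identically; the global p-value is the (count+1)/(nSim+1)
#' fraction of simulated RSS at or above the observed one.
#'
#' Outlier test: the same per-SNP simulated residuals give each SNP an
#' empirical p-value, Bonferroni-adjusted across SNPs; SNPs with adjusted
#' p < `outlierAlpha` are flagged, and the corrected estimate is the
#' heterogeneity-gated IVW rerun on exactly the non-flagged SNPs.
#'
#' Distortion test: the observed shift between corrected and raw estimates
#' is compared with the null distribution of shifts obtained by removing
#' random subsets of the same size (two-sided on the absolute shift).
#'
#' All randomness derives from `seed`; simulation draws are made in
#' variant-id order, so results do not depend on input row order.
#'
#' @param h a [HarmonizedSet-class] with at least 4 instruments.
#' @param nSim simulated replicates (default 1000, minimum 100). Note the
#'   smallest attainable Bonferroni-adjusted outlier p is
#'   n_snps/(nSim + 1), so `nSim` must be large enough for `outlierAlpha`
#'   to be reachable.
#' @param outlierAlpha threshold on Bonferroni-adjusted per-SNP p-values
#'   (default 0.05).
#' @param seed RNG seed (default 0).
#' @return A [PressoResult-class].
#' @export
mrPresso <- function(h, nSim = 1000, outlierAlpha = 0.05, seed = 0) {
  .checkH(h, 4L, "MR-PRESSO")
  if (nSim < 100)
    .mrStop("config_error", "MR-PRESSO needs nSim >= 100, got %d", nSim)
  nSim <- as.integer(nSim)
  n <- length(h)

  # canonical variant order makes the simulation order-invariant
  ord <- order(h@variantIds)
  bx <- h@betaExp[ord]; sx <- h@seExp[ord]
  by <- h@betaOut[ord]; sy <- h@seOut[ord]
  w <- 1 / sy^2

  thLoo <- .looSlopes(bx, by, w)
  residObs <- w * (by - thLoo * bx)^2
  rssObs <- sum(residObs)

  sim <- .withSeed(seed, {
    BX <- matrix(stats::rnorm(nSim * n, rep(bx, each = nSim),
                              rep(sx, each = nSim)), nSim, n)
    BY <- matrix(stats::rnorm(nSim * n, rep(thLoo * bx, each = nSim),
                              rep(sy, each = nSim)), nSim, n)
    W <- matrix(w, nSim, n, byrow = TRUE)
    sxyS <- rowSums(W * BX * BY)
    sxxS <- rowSums(W * BX^2)
    TH <- (sxyS - W * BX * BY) / (sxxS - W * BX^2)
    RES <- W * (BY - TH * BX)^2
    list(rss = rowSums(RES),
         exceed = colSums(RES >= matrix(residObs, nSim, n, byrow = TRUE)))
  })
  globalPval <- (sum(sim$rss >= rssObs) + 1) / (nSim + 1)
  pRaw <- (sim$exceed + 1) / (nSim + 1)
  pAdj <- pmin(1, pRaw * n)
  outSorted <- which(pAdj < outlierAlpha)
  outliers <- sort(ord[outSorted])            # back to input positions
  pAdjInput <- numeric(n)
  pAdjInput[ord] <- pAdj

  raw <- mrIVW(h, "auto")
  corrected <- NULL
  distortionPval <- NA_real_
  if (length(outliers)) {
    keep <- setdiff(seq_len(n), outliers)
    if (length(keep) < 2L)
      .mrStop("degenerate_correction",
              "MR-PRESSO flagged %d of %d instruments; no corrected estimate possible",
              length(outliers), n)
    corrected <- mrIVW(h[keep], "auto")
    dObs <- corrected@beta - raw@beta
    nOut <- length(outliers)
    dNull <- .withSeed(seed + 1L, {
      vapply(seq_len(nSim), function(b) {
        dropIdx <- sample.int(n, nOut)
        kb <- setdiff(seq_len(n), dropIdx)
        wk <- 1 / h@seOut[kb]^2
        sum(wk * h@betaExp[kb] * h@betaOut[kb]) /
          sum(wk * h@betaExp[kb]^2) - raw@beta
      }, numeric(1L))
    })
    distortionPval <- (sum(abs(dNull) >= abs(dObs)) + 1) / (nSim + 1)
  }
  new("PressoResult", globalRss = rssObs, globalPval = globalPval,
      outlierIndices = as.integer(outliers), outlierPvals = pAdjInput,
      distortionPval = distortionPval, estimateRaw = raw,
      estimateCorrected = corrected, nSim = nSim, seed = as.integer(seed))
}
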
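# Synthetic two-sample GWAS summary statistics with known causal structure.
#
# The generator emulates the structure of the real analyses this package
# targets: a large binary-trait exposure GWAS (hypothyroidism-scale,
# n ~ 405k), a large outcome GWAS (osteoporosis-scale, n ~ 399k), and a
# Nightingale-scale metabolite panel (n ~ 115k) for mediation. Per-variant
# standard errors follow the allele-frequency / sample-size coupling
# se = 1 / sqrt(2 maf (1 - maf) n).

#' Simulation configuration
#'
#' @param nSnps instruments with true exposure effects (default 100,
#'   matching the scale of a well-powered binary-trait exposure).
#' @param seed RNG seed (mandatory; every dataset is deterministic in it).
#' @param nExp,nOut exposure / outcome GWAS sample sizes driving the SE
#'   scale (defaults 405,357 and 399,054).
#' @param theta true causal effect of exposure on outcome, log-OR scale
#'   (default ln(1.092)).
#' @param mafRange uniform sampling interval for minor-allele frequencies,
#'   within (0, 0.5] (default 0.05-0.5).
#' @param effectMean,effectSd normal distribution of true per-allele
#'   instrument effects (default N(0.065, 0.015), calibrated so that a
#'   100-instrument set pools to roughly the 0.007 log-OR precision printed
#'   for mediator-step estimates at Nightingale-panel scale; instruments
#'   are comfortably strong, F far above 10).
#' @param pleiotropy one of [pleiotropyNone()], [pleiotropyBalanced()],
#'   [pleiotropyDirectional()], [pleiotropyCorrelated()].
#' @param propInvalid fraction of instruments carrying the pleiotropic
#'   effect (default 0).
#' @param nOutliers instruments given a gross outcome residual (default 0).
#' @param outlierMag outlier magnitude in units of the outcome SE
#'   (default 10).
#' @param nNullSnps additional variants with zero exposure effect, for
#'   exercising significance filtering (default 0).
#' @param mediationChain optional list from [mediationChain()].
#' @param ldBlocks optional list `list(blockSize =, r2 =)`: consecutive
#'   instruments form blocks of `blockSize` co-located, correlated variants
#'   (solely to exercise clumping).
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSnps = 100L, seed = 1L, nExp = 405357,
                             nOut = 399054, theta = log(1.092),
                             mafRange = c(0.05, 0.5), effectMean = 0.065,
                             effectSd = 0.015,
                             pleiotropy = pleiotropyNone(),
                             propInvalid = 0, nOutliers = 0L,
                             outlierMag = 10, nNullSnps = 0L,
                             mediationChain = NULL, ldBlocks = NULL) {
  stopifnot(.isCount(nSnps), nSnps >= 1, .isCount(nNullSnps),
            length(seed) == 1L, is.finite(seed),
            nExp > 0, nOut > 0, is.finite(theta),
            length(mafRange) == 2L, mafRange[1L] > 0, mafRange[2L] <= 0.5,
            mafRange[1L] <= mafRange[2L], effectSd >= 0,
            propInvalid >= 0, propInvalid <= 1,
            .isCount(nOutliers), outlierMag >= 0)
  if (!is.list(pleiotropy) || is.null(pleiotropy$type) ||
      !pleiotropy$type %in% c("none", "balanced", "directional", "correlated"))
    .mrStop("config_error", "invalid pleiotropy specification")
  if (!is.null(mediationChain))
    stopifnot(all(c("beta1", "beta2", "directEffect") %in%
                  names(mediationChain)))
  if (!is.null(ldBlocks))
    stopifnot(.isCount(ldBlocks$blockSize), ldBlocks$blockSize >= 1,
              ldBlocks$r2 >= 0, ldBlocks$r2 <= 1)
  structure(list(nSnps = as.integer(nSnps), seed = as.integer(seed),
                 nExp = nExp, nOut = nOut, theta = theta,
                 mafRange = mafRange, effectMean = effectMean,
                 effectSd = effectSd, pleiotropy = pleiotropy,
                 propInvalid = propInvalid, nOutliers = as.integer(nOutliers),
                 outlierMag = outlierMag, nNullSnps = as.integer(nNullSnps),
                 mediationChain = mediationChain, ldBlocks = ldBlocks),
            class = "SimulationConfig")
}

#' Pleiotropy regimes for the simulator
#'
#' `none`: all instruments valid. `balanced`: zero-mean normal direct
#' effects on the outcome (heterogeneity without bias). `directional`:
#' non-zero mean direct effects (biases IVW; Egger's InSIDE assumption
#' still holds). `correlated`: direct effects proportional to the
#' instrument strength plus noise (violates InSIDE).
#'
#' @param sd,mean normal parameters of the per-SNP direct effect.
#' @param strength proportionality constant linking direct effects to
#'   instrument effects.
#' @return list consumed by [simulationConfig()].
#' @export
pleiotropyNone <- function() list(type = "none")

#' @rdname pleiotropyNone
#' @export
pleiotropyBalanced <- function(sd) list(type = "balanced", sd = sd)

#' @rdname pleiotropyNone
#' @export
pleiotropyDirectional <- function(mean, sd) {
  list(type = "directional", mean = mean, sd = sd)
}

#' @rdname pleiotropyNone
#' @export
pleiotropyCorrelated <- function(strength) {
  list(type = "correlated", strength = strength)
}

#' Mediation-chain parameters
#'
#' @param beta1 exposure-to-mediator effect (default -0.02).
#' @param beta2 mediator-to-outcome effect (default -0.12).
#' @param directEffect exposure-to-outcome direct effect (default 0.086).
#'   The defaults give IE = 0.0024, TE = 0.0884 and a mediated proportion
#'   of about 2.7%, mirroring a small protective lipid-mediator chain.
#' @param nMed mediator GWAS sample size (default 115,078, the scale of
#'   the Nightingale metabolite panel).
#' @param nMedSnps instruments specific to the mediator (default 50).
#' @return list consumed by [simulationConfig()].
#' @export
mediationChain <- function(beta1 = -0.02, beta2 = -0.12,
                           directEffect = 0.086, nMed = 115078,
                           nMedSnps = 50L) {
  list(beta1 = beta1, beta2 = beta2, directEffect = directEffect,
       nMed = nMed, nMedSnps = as.integer(nMedSnps))
}

# non-palindromic allele pairs to draw from
.ALLELE_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                          "G", "A", "G", "T", "T", "C", "T", "G"),
                        ncol = 2L, byrow = TRUE)

# genome layout: chromosomes cycle 1..22, positions spaced far beyond any
# clumping window unless LD blocks are requested
.layoutSnps <- function(n, ids, ldBlocks = NULL) {
  if (is.null(ldBlocks)) {
    chrom <- as.character(rep_len(1:22, n))
    position <- 1e6 + 2.5e7 * (seq_len(n) - 1L) %/% 22L
  } else {
    b <- ldBlocks$blockSize
    block <- (seq_len(n) - 1L) %/% b
    within <- (seq_len(n) - 1L) %% b
    chrom <- as.character(rep_len(1:22, max(block) + 1L))[block + 1L]
    position <- 1e6 + 2.5e7 * (block %/% 22L) + 5e3 * within
  }
  pick <- sample.int(nrow(.ALLELE_PAIRS), n, replace = TRUE)
  data.frame(variant_id = ids, chromosome = chrom, position = position,
             effect_allele = .ALLELE_PAIRS[pick, 1L],
             other_allele = .ALLELE_PAIRS[pick, 2L],
             stringsAsFactors = FALSE)
}

.assoc <- function(layout, maf, betaHat, se, n) {
  data.frame(layout, eaf = maf, beta = betaHat, se = se,
             pval = .zp(betaHat, se), n = n, stringsAsFactors = FALSE,
             row.names = NULL)
}

.seFromMaf <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

# draw per-SNP pleiotropic direct effects for the invalid fraction
.drawPleiotropy <- function(cfg, gamma) {
  n <- length(gamma)
  alpha <- numeric(n)
  nInvalid <- round(cfg$propInvalid * n)
  pl <- cfg$pleiotropy
  if (pl$type == "none" || nInvalid == 0L)
    return(list(alpha = alpha, invalid = integer()))
  invalid <- sort(sample.int(n, nInvalid))
  alpha[invalid] <- switch(pl$type,
    balanced = stats::rnorm(nInvalid, 0, pl$sd),
    directional = stats::rnorm(nInvalid, pl$mean, pl$sd),
    correlated = pl$strength * gamma[invalid] +
      stats::rnorm(nInvalid, 0, abs(pl$strength * cfg$effectMean) / 4))
  list(alpha = alpha, invalid = invalid)
}

#' Simulate a univariable two-sample MR scenario
#'
#' Per instrument j: maf ~ U(mafRange); true effect gamma_j ~
#' N(effectMean, effectSd); observed exposure effect ~ N(gamma_j, seExp_j)
#' with seExp_j = 1/sqrt(2 maf(1-maf) nExp); pleiotropic direct effect
#' alpha_j on the invalid fraction; observed outcome effect ~
#' N(theta gamma_j + alpha_j, seOut_j), with `nOutliers` variants shifted
#' by `outlierMag` outcome SEs. Optional null variants have gamma = 0.
#' Wald-test p-values throughout; byte-identical output under one seed.
#'
#' @param cfg a [simulationConfig()].
#' @return list with elements `exposure` and `outcome`
#'   ([SummaryStats-class]), `ld` ([LdInfo-class]), and `truth` (list:
#'   theta, gamma, alpha, invalid/outlier indices, instrument ids).
#' @export
simulateUnivariable <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  .withSeed(cfg$seed, {
    n <- cfg$nSnps + cfg$nNullSnps
    ids <- sprintf("rs%07d", seq_len(n))
    layout <- .layoutSnps(n, ids, cfg$ldBlocks)
    maf <- stats::runif(n, cfg$mafRange[1L], cfg$mafRange[2L])
    gamma <- c(stats::rnorm(cfg$nSnps, cfg$effectMean, cfg$effectSd),
               numeric(cfg$nNullSnps))
    seX <- .seFromMaf(maf, cfg$nExp)
    bX <- stats::rnorm(n, gamma, seX)
    ple <- .drawPleiotropy(cfg, gamma)
    seY <- .seFromMaf(maf, cfg$nOut)
    bY <- stats::rnorm(n, cfg$theta * gamma + ple$alpha, seY)
    outlierIdx <- integer()
    if (cfg$nOutliers > 0L) {
      outlierIdx <- sort(sample.int(cfg$nSnps, min(cfg$nOutliers, cfg$nSnps)))
      sgn <- sample(c(-1, 1), length(outlierIdx), replace = TRUE)
      bY[outlierIdx] <- bY[outlierIdx] + sgn * cfg$outlierMag * seY[outlierIdx]
    }
    ld <- .blockLd(layout, cfg$ldBlocks)
    list(
      exposure = SummaryStats(.assoc(layout, maf, bX, seX, cfg$nExp),
                              traitId = "sim_exposure",
                              traitLabel = "simulated exposure",
                              sampleSize = cfg$nExp),
      outcome = SummaryStats(.assoc(layout, maf, bY, seY, cfg$nOut),
                             traitId = "sim_outcome",
                             traitLabel = "simulated outcome",
                             sampleSize = cfg$nOut),
      ld = ld,
      truth = list(theta = cfg$theta, gamma = gamma, alpha = ple$alpha,
                   invalid = ple$invalid, outliers = outlierIdx,
                   instrumentIds = ids[seq_len(cfg$nSnps)]))
  })
}

.blockLd <- function(layout, ldBlocks) {
  if (is.null(ldBlocks) || ldBlocks$blockSize < 2L) return(ldIndependent())
  n <- nrow(layout)
  b <- ldBlocks$blockSize
  block <- (seq_len(n) - 1L) %/% b
  pairs <- do.call(rbind, lapply(split(seq_len(n), block), function(idx) {
    if (length(idx) < 2L) return(NULL)
    cmb <- utils::combn(idx, 2L)
    data.frame(variant_a = layout$variant_id[cmb[1L, ]],
               variant_b = layout$variant_id[cmb[2L, ]],
               r2 = ldBlocks$r2, stringsAsFactors = FALSE)
  }))
  ldInfo(pairs)
}

#' Simulate an exposure-mediator-outcome chain
#'
#' The exposure's instruments also appear in the mediator GWAS (effects
#' beta1 * gamma_j) and the outcome GWAS (effects
#' (directEffect + beta1 * beta2) * gamma_j, so the implied total effect is
#' DE + IE). A separate set of instruments specific to the mediator is
#' generated for step-2 MR, with outcome effects beta2 * delta_j (those
#' variants affect the outcome only through the mediator).
#'
#' @param cfg a [simulationConfig()] with a `mediationChain`.
#' @return list with `exposure`, `mediator`, `outcome`
#'   ([SummaryStats-class]), `ld`, and `truth` (beta1, beta2, DE, IE, TE,
#'   proportion, instrument id sets). Truth identities IE = beta1*beta2
#'   and TE = DE + IE hold exactly by construction.
#' @export
simulateMediationChain <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  ch <- cfg$mediationChain
  if (is.null(ch))
    .mrStop("config_error", "simulateMediationChain needs cfg$mediationChain")
  .withSeed(cfg$seed, {
    n <- cfg$nSnps
    m <- ch$nMedSnps
    ids <- sprintf("rs%07d", seq_len(n))
    idsMed <- sprintf("rs9%06d", seq_len(m))
    layout <- .layoutSnps(n, ids, cfg$ldBlocks)
    layoutMed <- .layoutSnps(m, idsMed)
    maf <- stats::runif(n, cfg$mafRange[1L], cfg$mafRange[2L])
    mafMed <- stats::runif(m, cfg$mafRange[1L], cfg$mafRange[2L])
    gamma <- stats::rnorm(n, cfg$effectMean, cfg$effectSd)
    delta <- stats::rnorm(m, cfg$effectMean, cfg$effectSd)
    ie <- ch$beta1 * ch$beta2
    teSlope <- ch$directEffect + ie

    seX <- .seFromMaf(maf, cfg$nExp)
    bX <- stats::rnorm(n, gamma, seX)
    seM1 <- .seFromMaf(maf, ch$nMed)
    bM1 <- stats::rnorm(n, ch$beta1 * gamma, seM1)
    ple <- .drawPleiotropy(cfg, gamma)
    seY1 <- .seFromMaf(maf, cfg$nOut)
    bY1 <- stats::rnorm(n, teSlope * gamma + ple$alpha, seY1)
    seM2 <- .seFromMaf(mafMed, ch$nMed)
    bM2 <- stats::rnorm(m, delta, seM2)
    seY2 <- .seFromMaf(mafMed, cfg$nOut)
    bY2 <- stats::rnorm(m, ch$beta2 * delta, seY2)

    list(
      exposure = SummaryStats(.assoc(layout, maf, bX, seX, cfg$nExp),
                              traitId = "sim_exposure",
                              traitLabel = "simulated exposure",
                              sampleSize = cfg$nExp),
      mediator = SummaryStats(rbind(.assoc(layout, maf, bM1, seM1, ch$nMed),
                                    .assoc(layoutMed, mafMed, bM2, seM2,
                                           ch$nMed)),
                              traitId = "sim_mediator",
                              traitLabel = "simulated mediator",
                              sampleSize = ch$nMed),
      outcome = SummaryStats(rbind(.assoc(layout, maf, bY1, seY1, cfg$nOut),
                                   .assoc(layoutMed, mafMed, bY2, seY2,
                                          cfg$nOut)),
                             traitId = "sim_outcome",
                             traitLabel = "simulated outcome",
                             sampleSize = cfg$nOut),
      ld = ldIndependent(),
      truth = list(beta1 = ch$beta1, beta2 = ch$beta2,
                   DE = ch$directEffect, IE = ie, TE = ch$directEffect + ie,
                   proportion = ie / (ch$directEffect + ie),
                   exposureInstrumentIds = ids,
                   mediatorInstrumentIds = idsMed))
  })
}

#' Simulate a candidate-mediator panel
#'
#' `nTrue` mediators sit on real causal chains (parameters from
#' `cfg$mediationChain`); the remainder are nulls: their associations with
#' the exposure's instruments are pure noise and their own instruments
#' have no outcome effect. The single outcome dataset covers the
#' exposure's instruments and every mediator's own instruments.
#'
#' @param cfg a [simulationConfig()] with a `mediationChain`.
#' @param nMediators panel size (default 249, the scale of an NMR
#'   metabolite panel).
#' @param nTrue mediators on true chains (default 1).
#' @return list with `exposure`, `mediators` (named list of
#'   [SummaryStats-class]), `outcome`, `ld`, and `truth`
#'   (`trueMediators`, per-mediator proportions).
#' @export
simulateMetabolitePanel <- function(cfg, nMediators = 249L, nTrue = 1L) {
  stopifnot(inherits(cfg, "SimulationConfig"), nTrue <= nMediators,
            .isCount(nMediators), .isCount(nTrue), nMediators >= 1)
  ch <- cfg$mediationChain
  if (is.null(ch))
    .mrStop("config_error", "simulateMetabolitePanel needs cfg$mediationChain")
  .withSeed(cfg$seed, {
    n <- cfg$nSnps
    m <- ch$nMedSnps
    ids <- sprintf("rs%07d", seq_len(n))
    layout <- .layoutSnps(n, ids, NULL)
    maf <- stats::runif(n, cfg$mafRange[1L], cfg$mafRange[2L])
    gamma <- stats::rnorm(n, cfg$effectMean, cfg$effectSd)
    seX <- .seFromMaf(maf, cfg$nExp)
    bX <- stats::rnorm(n, gamma, seX)
    ie <- ch$beta1 * ch$beta2
    teSlope <- ch$directEffect + nTrue * ie
    seY <- .seFromMaf(maf, cfg$nOut)
    bY <- stats::rnorm(n, teSlope * gamma, seY)
    outRecords <- .assoc(layout, maf, bY, seY, cfg$nOut)
    trueFlag <- seq_len(nMediators) <= nTrue
    mediators <- vector("list", nMediators)
    for (i in seq_len(nMediators)) {
      medId <- sprintf("sim_met_%03d", i)
      idsMed <- sprintf("rs%03d%04d", i + 100L, seq_len(m))
      layoutMed <- .layoutSnps(m, idsMed)
      mafMed <- stats::runif(m, cfg$mafRange[1L], cfg$mafRange[2L])
      delta <- stats::rnorm(m, cfg$effectMean, cfg$effectSd)
      seM1 <- .seFromMaf(maf, ch$nMed)
      b1 <- if (trueFlag[i]) ch$beta1 else 0
      b2 <- if (trueFlag[i]) ch$beta2 else 0
      bM1 <- stats::rnorm(n, b1 * gamma, seM1)
      seM2 <- .seFromMaf(mafMed, ch$nMed)
      bM2 <- stats::rnorm(m, delta, seM2)
      seY2 <- .seFromMaf(mafMed, cfg$nOut)
      bY2 <- stats::rnorm(m, b2 * delta, seY2)
      mediators[[i]] <- SummaryStats(
        rbind(.assoc(layout, maf, bM1, seM1, ch$nMed),
              .assoc(layoutMed, mafMed, bM2, seM2, ch$nMed)),
        traitId = medId, traitLabel = medId, sampleSize = ch$nMed)
      outRecords <- rbind(outRecords,
                          .assoc(layoutMed, mafMed, bY2, seY2, cfg$nOut))
    }
    names(mediators) <- vapply(mediators, traitId, character(1L))
    list(
      exposure = SummaryStats(.assoc(layout, maf, bX, seX, cfg$nExp),
                              traitId = "sim_exposure",
                              traitLabel = "simulated exposure",
                              sampleSize = cfg$nExp),
      mediators = mediators,
      outcome = SummaryStats(outRecords, traitId = "sim_outcome",
                             traitLabel = "simulated outcome",
                             sampleSize = cfg$nOut),
      ld = ldIndependent(),
      truth = list(trueMediators = names(mediators)[trueFlag],
                   beta1 = ifelse(trueFlag, ch$beta1, 0),
                   beta2 = ifelse(trueFlag, ch$beta2, 0),
                   proportion = ifelse(trueFlag,
                                       ie / (ch$directEffect + nTrue * ie),
                                       0)))
  })
}

#' Simulate a multi-exposure scenario for multivariable MR
#'
#' Every variant carries an independent true effect on each exposure
#' (gamma_jk ~ N(0, `effectScatter`)); the outcome effect is the inner
#' product with the true direct effects plus noise. Returns both the
#' assembled [MvmrDataset-class] (true-frame, no selection) and the full
#' per-exposure [SummaryStats-class] objects for pipeline-level use.
#'
#' @param cfg a [simulationConfig()]; `nSnps`, `nExp`, `nOut`, `mafRange`
#'   and `seed` are used.
#' @param directEffects numeric vector of true direct effects, one per
#'   exposure (default `c(0.08, 0, 0.05)`).
#' @param effectScatter SD of the per-exposure true instrument effects
#'   (default 0.02).
#' @return list with `exposures` (list of [SummaryStats-class]),
#'   `outcome`, `dataset` ([MvmrDataset-class]) and `truth`.
#' @export
simulateMvmr <- function(cfg, directEffects = c(0.08, 0, 0.05),
                         effectScatter = 0.02) {
  stopifnot(inherits(cfg, "SimulationConfig"), length(directEffects) >= 2L)
  k <- length(directEffects)
  .withSeed(cfg$seed, {
    n <- cfg$nSnps
    ids <- sprintf("rs%07d", seq_len(n))
    layout <- .layoutSnps(n, ids, NULL)
    maf <- stats::runif(n, cfg$mafRange[1L], cfg$mafRange[2L])
    gamma <- matrix(stats::rnorm(n * k, 0, effectScatter), n, k)
    seX <- .seFromMaf(maf, cfg$nExp)
    bX <- gamma + matrix(stats::rnorm(n * k, 0, seX), n, k)
    seY <- .seFromMaf(maf, cfg$nOut)
    bY <- stats::rnorm(n, drop(gamma %*% directEffects), seY)
    expIds <- sprintf("sim_exposure_%d", seq_len(k))
    exposures <- lapply(seq_len(k), function(j)
      SummaryStats(.assoc(layout, maf, bX[, j], seX, cfg$nExp),
                   traitId = expIds[j], traitLabel = expIds[j],
                   sampleSize = cfg$nExp))
    seXm <- matrix(seX, n, k)
    dimnames(bX) <- dimnames(seXm) <- list(ids, expIds)
    dataset <- new("MvmrDataset", variantIds = ids, betaExp = bX,
                   seExp = seXm, betaOut = bY, seOut = seY,
                   exposureIds = expIds, outcomeId = "sim_outcome",
                   dropLog = data.frame(variant_id = character(),
                                        reason = character()))
    list(exposures = exposures,
         outcome = SummaryStats(.assoc(layout, maf, bY, seY, cfg$nOut),
                                traitId = "sim_outcome",
                                traitLabel = "simulated outcome",
                                sampleSize = cfg$nOut),
         dataset = dataset,
         truth = list(directEffects = directEffects, gamma = gamma))
  })
}

#' Write a simulation scenario to disk
#'
#' Emits each dataset as canonical summary-statistics TSV plus a truth JSON
#' (config echo and ground-truth fields) for harness consumption.
#'
#' @param sim result of a `simulate*()` call.
#' @param cfg the [simulationConfig()] that produced it.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim)) {
    obj <- sim[[nm]]
    if (is(obj, "SummaryStats"))
      writeSummaryStats(obj, file.path(dir, paste0(nm, ".tsv")))
    if (nm == "mediators" && is.list(obj))
      for (med in obj)
        writeSummaryStats(med, file.path(dir, paste0(traitId(med), ".tsv")))
  }
  jsonlite::write_json(list(config = unclass(cfg), truth = sim$truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}
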
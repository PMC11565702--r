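# End-to-end orchestration: config -> instruments -> harmonize -> estimate
# -> diagnose -> (MVMR) -> (mediation screen) -> report.

.REPORT_SCHEMA_VERSION <- "1.0"

.readDatasetCfg <- function(dc, what) {
  if (is.null(dc$path))
    .mrStop("config_error", "%s dataset needs a 'path'", what)
  readSummaryStats(dc$path, columnMap = dc$column_map,
                   traitId = if (is.null(dc$id)) basename(dc$path) else dc$id,
                   traitLabel = if (is.null(dc$label)) dc$id else dc$label,
                   sampleSize = if (is.null(dc$sample_size)) NA_real_
                                else dc$sample_size)
}

.ldFromCfg <- function(lc) {
  if (is.null(lc) || identical(lc$mode, "independent")) return(ldIndependent())
  if (!is.null(lc$path)) return(readLdInfo(lc$path))
  .mrStop("config_error", "ld config needs mode 'independent' or a 'path'")
}

.instrumentCfgFrom <- function(ic) {
  if (is.null(ic)) return(instrumentConfig())
  get0 <- function(nm, dflt) if (is.null(ic[[nm]])) dflt else ic[[nm]]
  instrumentConfig(pThreshold = get0("p_threshold", 5e-8),
                   clumpKb = get0("clump_kb", 10000),
                   clumpR2 = get0("clump_r2", 0.001),
                   fMin = get0("f_min", 10))
}

.stage <- function(name, expr) {
  withCallingHandlers(
    tryCatch(expr, mrchain_error = function(e) {
      code <- class(e)[1L]
      .mrStop("pipeline_failure", "stage '%s' failed [%s]: %s",
              name, code, conditionMessage(e))
    }),
    mrchain_warning = function(w) {
      message(sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
}

#' Run the full MR analysis pipeline
#'
#' Executes instrument selection, harmonization, the heterogeneity-gated
#' IVW as primary analysis alongside MR-Egger, weighted median, weighted
#' mode and MR-PRESSO, the diagnostic battery, and optionally multivariable
#' MR and a mediation screen, from a single configuration. All seeds are
#' explicit in the config, so reruns reproduce the report bit-identically.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Top-level keys: `exposure` / `outcome` (each `path`, optional
#'   `id`, `label`, `sample_size`, `column_map`), optional `ld` (`mode:
#'   independent` or `path`), `instruments` (`p_threshold`, `clump_kb`,
#'   `clump_r2`, `f_min`), `estimators` (`n_boot`, `phi`, `seed`),
#'   `diagnostics` (`n_sim`, `outlier_alpha`, `seed`), `harmonize`
#'   (`drop_palindromic`, `palindromic_eaf_window`), optional `mvmr`
#'   (`exposures`: list of dataset entries), optional `mediation`
#'   (`mediators`: list of dataset entries, `alpha`).
#' @return An [AnalysisReport-class]. `status` is `"completed-with-flags"`
#'   when heterogeneity, pleiotropy, a significant MR-PRESSO global test
#'   or weak instruments were flagged.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfgText <- yaml::as.yaml(config)

  exposure <- .stage("read_exposure", .readDatasetCfg(config$exposure, "exposure"))
  outcome <- .stage("read_outcome", .readDatasetCfg(config$outcome, "outcome"))
  ld <- .stage("ld", .ldFromCfg(config$ld))
  icfg <- .instrumentCfgFrom(config$instruments)
  ecfg <- config$estimators
  nBoot <- if (is.null(ecfg$n_boot)) 1000L else as.integer(ecfg$n_boot)
  phi <- if (is.null(ecfg$phi)) 1 else ecfg$phi
  estSeed <- if (is.null(ecfg$seed)) 0L else as.integer(ecfg$seed)
  dcfg <- config$diagnostics
  nSim <- if (is.null(dcfg$n_sim)) 1000L else as.integer(dcfg$n_sim)
  outlierAlpha <- if (is.null(dcfg$outlier_alpha)) 0.05 else dcfg$outlier_alpha
  diagSeed <- if (is.null(dcfg$seed)) 0L else as.integer(dcfg$seed)
  hcfg <- config$harmonize
  dropPal <- if (is.null(hcfg$drop_palindromic)) TRUE else hcfg$drop_palindromic
  palWin <- if (is.null(hcfg$palindromic_eaf_window)) 0.08
            else hcfg$palindromic_eaf_window

  flags <- character()
  instruments <- .stage("select_instruments",
                        selectInstruments(exposure, ld, icfg))
  meanF <- mean(fStatistics(instruments)$f)
  if (meanF <= 10) flags <- c(flags, "weak_instruments")
  h <- .stage("harmonize",
              harmonize(instruments, outcome, dropPal, palWin))

  ivw <- .stage("estimate", mrIVW(h, "auto"))
  egger <- .stage("estimate", mrEgger(h))
  wmed <- .stage("estimate", mrWeightedMedian(h, nBoot = nBoot, seed = estSeed))
  wmode <- .stage("estimate", mrWeightedMode(h, phi = phi, nBoot = nBoot,
                                             seed = estSeed))
  presso <- .stage("diagnostics", mrPresso(h, nSim = nSim,
                                           outlierAlpha = outlierAlpha,
                                           seed = diagSeed))
  het <- cochranQ(h)
  pleio <- pleiotropyTest(h)
  loo <- leaveOneOut(h)
  funnel <- funnelData(h)
  if (het@pval < 0.05) flags <- c(flags, "heterogeneity")
  if (pleio@pval < 0.05) flags <- c(flags, "pleiotropy")
  if (presso@globalPval < 0.05) flags <- c(flags, "presso_global")

  estRows <- list(as.data.frame(ivw), as.data.frame(egger),
                  as.data.frame(wmed), as.data.frame(wmode))
  rawRow <- as.data.frame(presso@estimateRaw)
  rawRow$method <- "mr_presso_raw"
  estRows <- c(estRows, list(rawRow))
  if (!is.null(presso@estimateCorrected)) {
    corRow <- as.data.frame(presso@estimateCorrected)
    corRow$method <- "mr_presso_corrected"
    estRows <- c(estRows, list(corRow))
  }
  estimates <- do.call(rbind, estRows)
  estimates <- cbind(exposure = traitId(exposure),
                     outcome = traitId(outcome), estimates,
                     stringsAsFactors = FALSE)

  mvmrRes <- NULL
  if (!is.null(config$mvmr)) {
    extra <- .stage("mvmr", lapply(config$mvmr$exposures, .readDatasetCfg,
                                   what = "mvmr exposure"))
    d <- .stage("mvmr", assembleMvmr(c(list(exposure), extra), outcome, ld,
                                     icfg, dropPal, palWin))
    mvmrRes <- .stage("mvmr", mvmrIVW(d))
  }

  mediationRes <- NULL
  if (!is.null(config$mediation)) {
    meds <- .stage("mediation", lapply(config$mediation$mediators,
                                       .readDatasetCfg, what = "mediator"))
    alpha <- if (is.null(config$mediation$alpha)) 0.05
             else config$mediation$alpha
    mediationRes <- .stage("mediation",
                           screenMediators(exposure, meds, outcome, ld, icfg,
                                           alpha = alpha, te = ivw,
                                           dropPalindromic = dropPal,
                                           palindromicEafWindow = palWin))
    attr(mediationRes, "results") <- NULL
    attr(mediationRes, "te") <- NULL
  }

  stageCounts <- instruments@meta$stages
  stageCounts <- rbind(stageCounts,
                       data.frame(stage = "harmonized", count = length(h)))
  new("AnalysisReport",
      estimates = estimates,
      diagnostics = list(
        heterogeneity = data.frame(Q = het@Q, df = het@df, pval = het@pval),
        pleiotropy = data.frame(intercept = pleio@intercept,
                                se = pleio@interceptSe, pval = pleio@pval),
        presso = data.frame(global_rss = presso@globalRss,
                            global_pval = presso@globalPval,
                            n_outliers = length(presso@outlierIndices),
                            distortion_pval = presso@distortionPval,
                            n_sim = presso@nSim, seed = presso@seed),
        presso_outliers = data.frame(
          variant_id = variantIds(h)[presso@outlierIndices],
          adj_pval = presso@outlierPvals[presso@outlierIndices]),
        leave_one_out = loo,
        funnel = funnel$points,
        funnel_lines = data.frame(
          ivw_beta = funnel$ivwBeta,
          egger_intercept = if (is.null(funnel$eggerIntercept)) NA_real_
                            else funnel$eggerIntercept,
          egger_slope = if (is.null(funnel$eggerSlope)) NA_real_
                        else funnel$eggerSlope)),
      mvmr = mvmrRes, mediation = mediationRes, stageCounts = stageCounts,
      provenance = list(schema_version = .REPORT_SCHEMA_VERSION,
                        config = config, config_hash = .fnv1a(cfgText),
                        seeds = list(estimators = estSeed,
                                     diagnostics = diagSeed),
                        package_version =
                          as.character(utils::packageVersion("mrchain"))),
      flags = flags,
      status = if (length(flags)) "completed-with-flags" else "completed")
}

#' Render an analysis report to files
#'
#' `tsv_bundle` writes one fixed-name TSV per table (`estimates.tsv`,
#' `heterogeneity.tsv`, `pleiotropy.tsv`, `presso.tsv`,
#' `presso_outliers.tsv`, `leave_one_out.tsv`, `funnel.tsv`,
#' `funnel_lines.tsv`, `stage_counts.tsv`, plus `mvmr.tsv` /
#' `mediation_screen.tsv` when present) and a `run_log.tsv` of status and
#' flags. `json` writes the whole report as one schema-versioned document,
#' readable back with [readAnalysisReport()].
#'
#' @param report an [AnalysisReport-class].
#' @param dir output directory (created if needed).
#' @param format `"tsv_bundle"` or `"json"`.
#' @return character vector of written paths, invisibly.
#' @export
renderReport <- function(report, dir, format = c("tsv_bundle", "json")) {
  format <- match.arg(format)
  stopifnot(is(report, "AnalysisReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
  }
  if (format == "tsv_bundle") {
    put(report@estimates, "estimates.tsv")
    for (nm in names(report@diagnostics))
      put(report@diagnostics[[nm]],
          paste0(sub("leave_one_out", "leave_one_out", nm), ".tsv"))
    put(report@stageCounts, "stage_counts.tsv")
    if (!is.null(report@mvmr)) put(as.data.frame(report@mvmr), "mvmr.tsv")
    if (!is.null(report@mediation))
      put(report@mediation, "mediation_screen.tsv")
    put(data.frame(key = c("status", "flags", "config_hash",
                           "package_version"),
                   value = c(report@status,
                             paste(report@flags, collapse = ","),
                             report@provenance$config_hash,
                             report@provenance$package_version)),
        "run_log.tsv")
  } else {
    path <- file.path(dir, "report.json")
    payload <- list(schema_version = .REPORT_SCHEMA_VERSION,
                    status = report@status, flags = report@flags,
                    estimates = report@estimates,
                    diagnostics = report@diagnostics,
                    mvmr = if (is.null(report@mvmr)) NULL
                           else list(table = as.data.frame(report@mvmr),
                                     n_snps = report@mvmr@nSnps,
                                     exposure_ids = report@mvmr@exposureIds),
                    mediation = report@mediation,
                    stage_counts = report@stageCounts,
                    provenance = report@provenance)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
    written <- path
  }
  invisible(written)
}

#' Read a JSON analysis report back into an AnalysisReport
#'
#' @param path a `report.json` written by [renderReport()].
#' @return An [AnalysisReport-class].
#' @export
readAnalysisReport <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  asDf <- function(x) as.data.frame(x, stringsAsFactors = FALSE)
  diag <- lapply(p$diagnostics, asDf)
  mvmr <- NULL
  if (!is.null(p$mvmr))
    mvmr <- new("MvmrEstimate", table = asDf(p$mvmr$table),
                nSnps = as.integer(p$mvmr$n_snps),
                exposureIds = p$mvmr$exposure_ids)
  new("AnalysisReport", estimates = asDf(p$estimates), diagnostics = diag,
      mvmr = mvmr,
      mediation = if (is.null(p$mediation)) NULL else asDf(p$mediation),
      stageCounts = asDf(p$stage_counts), provenance = p$provenance,
      flags = as.character(unlist(p$flags)), status = p$status)
}
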
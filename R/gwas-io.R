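# Reading, writing and harmonizing GWAS summary statistics.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.isPalindromic <- function(ea, oa) {
  one <- nchar(ea) == 1L & nchar(oa) == 1L
  out <- rep(FALSE, length(ea))
  out[one] <- unname(.COMPLEMENT[ea[one]]) == oa[one]
  out
}

#' Read GWAS summary statistics from delimited text
#'
#' Accepts tab- or comma-delimited files (auto-detected from the header
#' line). Column names are mapped onto the canonical schema through
#' `columnMap`; rows violating the per-variant invariants (non-positive SE,
#' p-value outside (0,1], identical alleles, allele frequency outside
#' \[0,1\], duplicated variant id, unparseable numbers) are dropped and
#' tallied in the returned object's `meta` rather than failing the read.
#'
#' @param path file to read.
#' @param columnMap named character vector mapping canonical field names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) to the file's column
#'   names; defaults to the identity for names present in the file.
#' @param traitId,traitLabel,sampleSize dataset metadata.
#' @return A [SummaryStats-class]; `meta(x)$dropped` counts invalid rows by
#'   reason.
#' @seealso [writeSummaryStats()], [harmonize()]
#' @export
readSummaryStats <- function(path, columnMap = NULL, traitId = basename(path),
                             traitLabel = traitId, sampleSize = NA_real_) {
  if (!file.exists(path))
    .mrStop("io_error", "summary-statistics file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE)
  mandatory <- c("variant_id", "chromosome", "position", "effect_allele",
                 "other_allele", "beta", "se", "pval")
  optional <- c("eaf", "n")
  map <- stats::setNames(.SUMSTAT_COLUMNS, .SUMSTAT_COLUMNS)
  if (!is.null(columnMap)) {
    bad <- setdiff(names(columnMap), .SUMSTAT_COLUMNS)
    if (length(bad))
      .mrStop("config_error", "unknown canonical field(s) in columnMap: %s",
              paste(bad, collapse = ", "))
    map[names(columnMap)] <- unlist(columnMap)
  }
  missingMand <- mandatory[!map[mandatory] %in% names(raw)]
  if (length(missingMand))
    .mrStop("config_error",
            "mandatory column(s) absent from %s: %s (looked for: %s)",
            path, paste(missingMand, collapse = ", "),
            paste(map[missingMand], collapse = ", "))
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in .SUMSTAT_COLUMNS) {
    src <- map[[field]]
    df[[field]] <- if (src %in% names(raw)) raw[[src]]
                   else NA_character_
  }
  numify <- function(x) suppressWarnings(as.numeric(x))
  parsed <- data.frame(
    variant_id = as.character(df$variant_id),
    chromosome = as.character(df$chromosome),
    position = numify(df$position),
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele = toupper(as.character(df$other_allele)),
    eaf = numify(df$eaf), beta = numify(df$beta), se = numify(df$se),
    pval = numify(df$pval), n = numify(df$n), stringsAsFactors = FALSE)

  reason <- rep(NA_character_, nrow(parsed))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- why
  }
  flag(is.na(parsed$variant_id) | parsed$variant_id == "", "missing_variant_id")
  flag(is.na(parsed$beta), "missing_beta")
  flag(is.na(parsed$se) | parsed$se <= 0, "invalid_se")
  flag(is.na(parsed$pval) | parsed$pval <= 0 | parsed$pval > 1, "invalid_pval")
  flag(!grepl(.ALLELE_RE, parsed$effect_allele) |
       !grepl(.ALLELE_RE, parsed$other_allele), "invalid_alleles")
  flag(parsed$effect_allele == parsed$other_allele, "identical_alleles")
  flag(!is.na(parsed$eaf) & (parsed$eaf < 0 | parsed$eaf > 1), "invalid_eaf")
  flag(!is.na(parsed$position) & parsed$position < 0, "invalid_position")
  dup <- duplicated(parsed$variant_id)
  reason[is.na(reason) & dup] <- "duplicate_variant_id"

  keep <- is.na(reason)
  if (!any(keep))
    .mrStop("empty_dataset", "no valid summary-statistic rows in %s", path)
  tally <- table(reason[!keep])
  SummaryStats(parsed[keep, , drop = FALSE], traitId = traitId,
               traitLabel = traitLabel, sampleSize = sampleSize,
               meta = list(path = path, nRead = nrow(parsed),
                           nDropped = sum(!keep),
                           dropped = stats::setNames(as.integer(tally),
                                                     names(tally))))
}

#' Write summary statistics as canonical TSV
#'
#' Emits the fixed column order (`variant_id`, `chromosome`, `position`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`).
#' Doubles are serialized at full precision (17 significant digits) so that
#' `readSummaryStats(writeSummaryStats(x))` reproduces `x` field-for-field
#' and a second write is byte-identical; missing values appear as `NA`.
#'
#' @param x a [SummaryStats-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(is(x, "SummaryStats"))
  r <- records(x)
  cols <- cbind(
    r$variant_id,
    ifelse(is.na(r$chromosome), "NA", r$chromosome),
    .fmtInt(r$position),
    r$effect_allele, r$other_allele,
    .fmtNum(r$eaf), .fmtNum(r$beta), .fmtNum(r$se), .fmtNum(r$pval),
    .fmtInt(r$n))
  lines <- c(paste(.SUMSTAT_COLUMNS, collapse = "\t"),
             if (nrow(r)) apply(cols, 1L, paste, collapse = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    .mrStop("io_error", "failed writing summary statistics to %s: %s",
            path, conditionMessage(ok))
  invisible(path)
}

#' Export a harmonization drop log as TSV
#'
#' @param x a [HarmonizedSet-class] or [MvmrDataset-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeDropLog <- function(x, path) {
  utils::write.table(dropLog(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome onto a shared effect-allele frame
#'
#' Restricts to variants present in both datasets (matched by variant id),
#' flips the outcome effect sign (and complements its allele frequency) when
#' the outcome's effect/other alleles are swapped relative to the exposure,
#' and drops irreconcilable allele pairs as `mismatch`. Palindromic variants
#' (A/T or C/G) are dropped outright when `dropPalindromic = TRUE` (the
#' default, the conservative reading of palindrome removal); with the opt-in
#' relaxation they are retained only when both allele frequencies are
#' informative (present and farther than `palindromicEafWindow` from 0.5),
#' in which case discordant frequencies trigger a strand flip of the outcome
#' effect. Strand (complement-base) rescue is never attempted. Every removed
#' variant is recorded in the drop log with its reason.
#'
#' @param exposure,outcome [SummaryStats-class] objects.
#' @param dropPalindromic drop all palindromic variants (default `TRUE`).
#' @param palindromicEafWindow half-width around 0.5 inside which an allele
#'   frequency is considered uninformative (default 0.08).
#' @return A [HarmonizedSet-class].
#' @examples
#' exp <- SummaryStats(data.frame(
#'   variant_id = c("rs1", "rs2"), chromosome = "1",
#'   position = c(100L, 200L), effect_allele = c("A", "C"),
#'   other_allele = c("G", "T"), eaf = 0.3, beta = c(0.1, 0.12),
#'   se = 0.01, pval = 1e-10, n = 1000L), traitId = "exp")
#' out <- SummaryStats(data.frame(
#'   variant_id = c("rs1", "rs2"), chromosome = "1",
#'   position = c(100L, 200L), effect_allele = c("G", "C"),
#'   other_allele = c("A", "T"), eaf = 0.7, beta = c(0.05, 0.01),
#'   se = 0.02, pval = 0.01, n = 1000L), traitId = "out")
#' h <- harmonize(exp, out)
#' betaOut(h)  # rs1 flipped to -0.05
#' @export
harmonize <- function(exposure, outcome, dropPalindromic = TRUE,
                      palindromicEafWindow = 0.08) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"))
  re <- records(exposure)
  ro <- records(outcome)
  shared <- re$variant_id[re$variant_id %in% ro$variant_id]
  if (!length(shared))
    .mrStop("empty_overlap", "no shared variants between '%s' and '%s'",
            traitId(exposure), traitId(outcome))
  e <- re[match(shared, re$variant_id), , drop = FALSE]
  o <- ro[match(shared, ro$variant_id), , drop = FALSE]

  aligned <- o$effect_allele == e$effect_allele &
             o$other_allele == e$other_allele
  swapped <- o$effect_allele == e$other_allele &
             o$other_allele == e$effect_allele & !aligned
  betaOutAdj <- ifelse(swapped, -o$beta, o$beta)
  eafOutAdj <- ifelse(swapped & !is.na(o$eaf), 1 - o$eaf, o$eaf)

  reason <- rep(NA_character_, length(shared))
  reason[!aligned & !swapped] <- "mismatch"

  pal <- .isPalindromic(e$effect_allele, e$other_allele) & is.na(reason)
  if (any(pal)) {
    if (dropPalindromic) {
      reason[pal] <- "palindromic"
    } else {
      uninf <- function(f) is.na(f) | abs(f - 0.5) <= palindromicEafWindow
      ambiguous <- pal & (uninf(e$eaf) | uninf(eafOutAdj))
      reason[ambiguous] <- "palindromic"
      flip <- pal & !ambiguous & (e$eaf - 0.5) * (eafOutAdj - 0.5) < 0
      betaOutAdj[flip] <- -betaOutAdj[flip]
      eafOutAdj[flip] <- 1 - eafOutAdj[flip]
    }
  }

  keep <- is.na(reason)
  drop <- data.frame(variant_id = shared[!keep], reason = reason[!keep],
                     stringsAsFactors = FALSE)
  if (!any(keep))
    .mrStop("empty_overlap",
            "all %d shared variants between '%s' and '%s' were dropped (%s)",
            length(shared), traitId(exposure), traitId(outcome),
            paste(unique(drop$reason), collapse = ", "))
  HarmonizedSet(shared[keep], e$beta[keep], e$se[keep],
                betaOutAdj[keep], o$se[keep],
                exposureId = traitId(exposure), outcomeId = traitId(outcome),
                dropLog = drop)
}
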
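# Instrument selection: genome-wide significance, LD clumping, F-statistics.

#' Declare all candidate variants mutually independent
#'
#' @return An [LdInfo-class] in `independent` mode: clumping then removes
#'   only exact positional duplicates.
#' @export
ldIndependent <- function() {
  new("LdInfo", mode = "independent",
      pairs = data.frame(variant_a = character(), variant_b = character(),
                         r2 = numeric()))
}

#' Build pairwise LD information from a long table or square matrix
#'
#' @param x either a data.frame with columns `variant_a`, `variant_b`, `r2`,
#'   or a square numeric matrix with variant ids as dimnames.
#' @return An [LdInfo-class] in `pairs` mode. The lookup is symmetric;
#'   pairs absent from the table have unknown LD.
#' @export
ldInfo <- function(x) {
  if (is.matrix(x)) {
    ids <- rownames(x)
    if (is.null(ids) || !identical(ids, colnames(x)))
      .mrStop("config_error",
              "LD matrix needs identical variant-id row and column names")
    idx <- which(upper.tri(x), arr.ind = TRUE)
    x <- data.frame(variant_a = ids[idx[, 1L]], variant_b = ids[idx[, 2L]],
                    r2 = x[idx], stringsAsFactors = FALSE)
  }
  new("LdInfo", mode = "pairs",
      pairs = data.frame(variant_a = as.character(x$variant_a),
                         variant_b = as.character(x$variant_b),
                         r2 = as.numeric(x$r2), stringsAsFactors = FALSE))
}

#' Read LD information from a file
#'
#' Accepts the 3-column long format (`variant_a`, `variant_b`, `r2`, TSV) or
#' a square r-squared matrix whose first column holds variant ids matching
#' the header.
#'
#' @param path file to read.
#' @return An [LdInfo-class].
#' @export
readLdInfo <- function(path) {
  if (!file.exists(path)) .mrStop("io_error", "LD file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("variant_a", "variant_b", "r2") %in% names(tab)))
    return(ldInfo(tab))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  ldInfo(m)
}

# symmetric lookup of r2 for vectors of id pairs; NA when unknown
.ldLookup <- function(ld, a, b) {
  if (ld@mode == "independent") return(rep(NA_real_, length(a)))
  p <- ld@pairs
  key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\r")
  tab <- stats::setNames(p$r2, key(p$variant_a, p$variant_b))
  unname(tab[key(a, b)])
}

#' Filter to genome-wide-significant associations
#'
#' Retains exactly the records with `pval < pThreshold` (strict inequality),
#' preserving input order.
#'
#' @param x a [SummaryStats-class].
#' @param pThreshold significance threshold, default 5e-8.
#' @return A [SummaryStats-class]; possibly empty.
#' @export
filterSignificance <- function(x, pThreshold = 5e-8) {
  stopifnot(is(x, "SummaryStats"))
  r <- records(x)
  SummaryStats(r[r$pval < pThreshold, , drop = FALSE], traitId = traitId(x),
               traitLabel = traitLabel(x), sampleSize = x@sampleSize,
               meta = x@meta)
}

#' Per-variant instrument-strength F-statistics
#'
#' The single-SNP F-statistic is computed as beta^2 / se^2; it is invariant
#' to the sign of beta.
#'
#' @param x a [SummaryStats-class].
#' @return data.frame with columns `variant_id` and `f`.
#' @export
fStatistics <- function(x) {
  stopifnot(is(x, "SummaryStats"))
  r <- records(x)
  data.frame(variant_id = r$variant_id, f = r$beta^2 / r$se^2,
             stringsAsFactors = FALSE)
}

# Greedy clumping core over a candidate table. Returns retained variant ids
# in selection order (ascending index p, ties by variant id).
.greedyClump <- function(cand, ld, clumpKb, clumpR2,
                         missingLd = c("linked", "error")) {
  missingLd <- match.arg(missingLd)
  if (!nrow(cand)) return(character())
  ord <- order(cand$pval, cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  n <- nrow(cand)
  alive <- rep(TRUE, n)
  kept <- character()
  window <- clumpKb * 1000
  for (i in seq_len(n)) {
    if (!alive[i]) next
    kept <- c(kept, cand$variant_id[i])
    if (i == n) break
    j <- which(alive & seq_len(n) > i &
               cand$chromosome == cand$chromosome[i] &
               !is.na(cand$position) & !is.na(cand$position[i]) &
               abs(cand$position - cand$position[i]) <= window)
    if (!length(j)) next
    if (ld@mode == "independent") {
      dupPos <- j[cand$position[j] == cand$position[i]]
      alive[dupPos] <- FALSE
    } else {
      r2 <- .ldLookup(ld, rep(cand$variant_id[i], length(j)),
                      cand$variant_id[j])
      if (any(is.na(r2))) {
        if (missingLd == "error")
          .mrStop("missing_ld",
                  "no r2 for pair(s) %s - %s within the clumping window",
                  cand$variant_id[i],
                  paste(cand$variant_id[j][is.na(r2)], collapse = ", "))
        r2[is.na(r2)] <- 1  # treat-as-linked default
      }
      alive[j[r2 > clumpR2]] <- FALSE
    }
  }
  kept
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p remaining variant as an index (p-value
#' ties broken by variant id) and removes all remaining variants on the same
#' chromosome within `clumpKb` kilobases whose r-squared with the index
#' exceeds `clumpR2`. In `independent` mode only same-position duplicates
#' are removed. Output order is canonical (ascending p), so the result does
#' not depend on input row order.
#'
#' @param x a [SummaryStats-class] of candidate variants.
#' @param ld an [LdInfo-class].
#' @param clumpKb physical window in kilobases (default 10,000).
#' @param clumpR2 r-squared threshold (default 0.001).
#' @param missingLd policy when a same-window pair has no r2 entry:
#'   `"linked"` removes the dependent variant (default), `"error"` aborts.
#' @return A [SummaryStats-class] of index variants.
#' @export
clumpVariants <- function(x, ld = ldIndependent(), clumpKb = 10000,
                          clumpR2 = 0.001, missingLd = c("linked", "error")) {
  stopifnot(is(x, "SummaryStats"), is(ld, "LdInfo"))
  r <- records(x)
  kept <- .greedyClump(r[, c("variant_id", "chromosome", "position", "pval")],
                       ld, clumpKb, clumpR2, missingLd)
  SummaryStats(r[match(kept, r$variant_id), , drop = FALSE],
               traitId = traitId(x), traitLabel = traitLabel(x),
               sampleSize = x@sampleSize, meta = x@meta)
}

#' Select instrumental variables
#'
#' Composition of the three instrument assumptions: genome-wide significance
#' (`pval < pThreshold`), mutual independence (greedy LD clumping), and
#' instrument strength (`F > fMin`, with `F = beta^2/se^2`). Stage counts
#' are recorded in the result's `meta$stages`, alongside the per-variant F
#' table in `meta$fTable`.
#'
#' @param x a [SummaryStats-class].
#' @param ld an [LdInfo-class].
#' @param cfg an [InstrumentConfig-class].
#' @param missingLd clumping policy for unknown same-window LD.
#' @return A [SummaryStats-class] of selected instruments.
#' @export
selectInstruments <- function(x, ld = ldIndependent(),
                              cfg = instrumentConfig(),
                              missingLd = c("linked", "error")) {
  stopifnot(is(x, "SummaryStats"), is(cfg, "InstrumentConfig"))
  validObject(cfg)
  sig <- filterSignificance(x, cfg@pThreshold)
  if (!nVariants(sig))
    .mrStop("no_instruments",
            "no variant of '%s' passes p < %g (significance stage)",
            traitId(x), cfg@pThreshold)
  clumped <- clumpVariants(sig, ld, cfg@clumpKb, cfg@clumpR2, missingLd)
  if (!nVariants(clumped))
    .mrStop("no_instruments", "clumping stage left no variant for '%s'",
            traitId(x))
  f <- fStatistics(clumped)
  strongIds <- f$variant_id[f$f > cfg@fMin]
  r <- records(clumped)
  strong <- r[r$variant_id %in% strongIds, , drop = FALSE]
  if (!nrow(strong))
    .mrStop("no_instruments",
            "no variant of '%s' has F > %g (strength stage)",
            traitId(x), cfg@fMin)
  stages <- data.frame(
    stage = c("input", "significant", "clumped", "strong"),
    count = c(nVariants(x), nVariants(sig), nVariants(clumped), nrow(strong)),
    stringsAsFactors = FALSE)
  meta <- x@meta
  meta$stages <- stages
  meta$fTable <- f
  SummaryStats(strong, traitId = traitId(x), traitLabel = traitLabel(x),
               sampleSize = x@sampleSize, meta = meta)
}
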
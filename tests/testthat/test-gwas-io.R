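# Reading, writing and harmonizing summary statistics.

test_that("TSV round trip is the identity, including missing values", {
  r <- makeRecords(sprintf("rs%d", 1:5), beta = c(0.1, -0.2, 0.05, 0, 1.3),
                   se = 0.01)
  r$eaf[2] <- NA
  r$n[4] <- NA
  ss <- SummaryStats(r, traitId = "t1")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryStats(ss, path)
  back <- readSummaryStats(path, traitId = "t1")
  expect_identical(records(back), records(ss))
  expect_true(is.na(records(back)$eaf[2]))
})

test_that("a large simulated dataset survives write-read-write byte-identically", {
  sim <- simulateUnivariable(simulationConfig(nSnps = 2000L, seed = 11L))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryStats(sim$exposure, p1)
  writeSummaryStats(readSummaryStats(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("comma-delimited input with remapped headers reads identically", {
  r <- makeRecords(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, -0.3), se = 0.02)
  ss <- SummaryStats(r, traitId = "x")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryStats(ss, tsv)
  csvLines <- gsub("\t", ",", readLines(tsv))
  csvLines[1] <- "SNP,CHR,BP,A1,A2,FRQ,BETA,SE,P,N"
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(csvLines, csv)
  back <- readSummaryStats(csv, columnMap = c(
    variant_id = "SNP", chromosome = "CHR", position = "BP",
    effect_allele = "A1", other_allele = "A2", eaf = "FRQ",
    beta = "BETA", se = "SE", pval = "P", n = "N"), traitId = "x")
  expect_identical(records(back), records(ss))
})

test_that("invalid rows are dropped and tallied, not fatal", {
  r <- makeRecords(sprintf("rs%d", 1:4), beta = 0.1, se = 0.01)
  r$se[2] <- 0                       # invalid
  r$pval[3] <- 0                     # invalid
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSummaryStats(path)
  expect_equal(nVariants(ss), 2L)
  expect_equal(ss@meta$nDropped, 2L)
  expect_equal(unname(ss@meta$dropped[["invalid_se"]]), 1L)
})

test_that("missing mandatory columns and empty datasets raise classed errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tbeta", "rs1\t0.1"), path)
  expect_error(readSummaryStats(path), class = "mrchain_config_error")
  r <- makeRecords("rs1", beta = 0.1, se = -1)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(r, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSummaryStats(path2), class = "mrchain_empty_dataset")
})

test_that("harmonize flips swapped alleles and complements eaf", {
  e <- makeStats("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "G",
                 traitId = "exp")
  o <- SummaryStats(makeRecords("rs1", beta = 0.05, se = 0.02, ea = "G",
                                oa = "A", eaf = 0.7), traitId = "out")
  h <- harmonize(e, o)
  expect_equal(betaOut(h), -0.05)
  expect_equal(betaExp(h), 0.1)
  expect_equal(nrow(dropLog(h)), 0L)
})

test_that("palindromic and mismatched variants are dropped with reasons", {
  e <- SummaryStats(makeRecords(c("rs1", "rs2", "rs3"),
                                beta = c(0.1, 0.2, 0.3), se = 0.01,
                                ea = c("A", "A", "A"),
                                oa = c("T", "G", "G")), traitId = "exp")
  o <- SummaryStats(makeRecords(c("rs1", "rs2", "rs3"),
                                beta = c(0.1, 0.2, 0.3), se = 0.01,
                                ea = c("A", "A", "A"),
                                oa = c("T", "G", "C")), traitId = "out")
  h <- harmonize(e, o, dropPalindromic = TRUE)
  expect_equal(variantIds(h), "rs2")
  dl <- dropLog(h)
  expect_equal(dl$reason[dl$variant_id == "rs1"], "palindromic")
  expect_equal(dl$reason[dl$variant_id == "rs3"], "mismatch")
})

test_that("palindrome relaxation keeps frequency-informative variants", {
  e <- SummaryStats(makeRecords(c("rs1", "rs2"), beta = c(0.1, 0.2),
                                se = 0.01, ea = "A", oa = "T",
                                eaf = c(0.2, 0.52)), traitId = "exp")
  o <- SummaryStats(makeRecords(c("rs1", "rs2"), beta = c(0.3, 0.4),
                                se = 0.01, ea = "A", oa = "T",
                                eaf = c(0.8, 0.48)), traitId = "out")
  h <- harmonize(e, o, dropPalindromic = FALSE, palindromicEafWindow = 0.08)
  # rs1 informative but discordant -> strand flip; rs2 near 0.5 -> dropped
  expect_equal(variantIds(h), "rs1")
  expect_equal(betaOut(h), -0.3)
  expect_equal(dropLog(h)$reason, "palindromic")
})

test_that("empty overlap names both datasets", {
  e <- makeStats("rs1", beta = 0.1, se = 0.01, traitId = "expA")
  o <- makeStats("rs2", beta = 0.1, se = 0.01, traitId = "outB")
  err <- expect_error(harmonize(e, o), class = "mrchain_empty_overlap")
  expect_match(conditionMessage(err), "expA")
  expect_match(conditionMessage(err), "outB")
})

test_that("harmonization bookkeeping: retained + dropped = intersection; idempotence; sign involution", {
  set.seed(401)
  for (rep in 1:20) {
    n <- 30
    ids <- sprintf("rs%03d", 1:n)
    pairIdx <- sample(8, n, replace = TRUE)
    pairs <- matrix(c("A","C","A","G","C","A","C","T",
                      "G","A","G","T","A","T","C","G"), ncol = 2, byrow = TRUE)
    e <- SummaryStats(makeRecords(ids, beta = rnorm(n), se = 0.01,
                                  ea = pairs[pairIdx, 1], oa = pairs[pairIdx, 2],
                                  eaf = runif(n)), traitId = "e")
    swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ro <- records(e)
    ro[swap, c("effect_allele", "other_allele")] <-
      ro[swap, c("other_allele", "effect_allele")]
    ro$beta <- ifelse(swap, -rnorm(n), rnorm(n))
    ro$eaf <- ifelse(swap, 1 - ro$eaf, ro$eaf)
    keepO <- sample(n, 25)
    o <- SummaryStats(ro[keepO, ], traitId = "o")
    h <- harmonize(e, o)
    inter <- length(intersect(ids, records(o)$variant_id))
    expect_equal(length(h) + nrow(dropLog(h)), inter)

    # idempotence: re-harmonizing the harmonized (already aligned) pair
    re <- records(e)[match(variantIds(h), ids), ]
    e2 <- SummaryStats(re, traitId = "e")
    ro2 <- re
    ro2$beta <- betaOut(h)
    ro2$se <- seOut(h)
    o2 <- SummaryStats(ro2, traitId = "o")
    h2 <- harmonize(e2, o2, dropPalindromic = FALSE,
                    palindromicEafWindow = 0)
    expect_equal(betaOut(h2), betaOut(h))
    expect_equal(betaExp(h2), betaExp(h))

    # involution: flipping both datasets' orientation preserves products
    flipStats <- function(s) {
      r <- records(s)
      r[, c("effect_allele", "other_allele")] <-
        r[, c("other_allele", "effect_allele")]
      r$beta <- -r$beta
      r$eaf <- 1 - r$eaf
      SummaryStats(r, traitId = traitId(s))
    }
    h3 <- harmonize(flipStats(e), flipStats(o))
    expect_equal(sort(variantIds(h3)), sort(variantIds(h)))
    m <- match(variantIds(h), variantIds(h3))
    expect_equal(betaExp(h3)[m] * betaOut(h3)[m], betaExp(h) * betaOut(h))
  }
})
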
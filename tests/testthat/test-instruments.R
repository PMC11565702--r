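# Instrument selection: significance, clumping, F-statistics.

test_that("significance filter uses strict inequality and preserves order", {
  ss <- makeStats(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                  pval = c(1e-9, 1e-7, 1e-8))
  kept <- filterSignificance(ss, 5e-8)
  expect_equal(records(kept)$variant_id, c("rs1", "rs3"))
  none <- filterSignificance(makeStats(c("a", "b"), beta = 0.1, se = 0.01,
                                       pval = c(0.5, 0.5)))
  expect_equal(nVariants(none), 0L)
})

test_that("F-statistics follow beta^2/se^2 and ignore the sign of beta", {
  ss <- makeStats(c("rs1", "rs2", "rs3"),
                  beta = c(0.1, 0, 0.03), se = c(0.01, 0.05, 0.02))
  f <- fStatistics(ss)
  expect_equal(f$f, c(100, 0, 2.25))
  neg <- makeStats(c("rs1", "rs2", "rs3"),
                   beta = -c(0.1, 0, 0.03), se = c(0.01, 0.05, 0.02))
  expect_equal(fStatistics(neg)$f, f$f)
})

test_that("greedy clumping keeps the smaller-p member of a linked pair", {
  ss <- makeStats(c("rs1", "rs2"), beta = c(0.2, 0.1), se = 0.01,
                  pval = c(1e-20, 1e-9), pos = c(1e6, 1e6 + 5e3))
  ld <- ldInfo(data.frame(variant_a = "rs1", variant_b = "rs2", r2 = 0.9))
  out <- clumpVariants(ss, ld)
  expect_equal(records(out)$variant_id, "rs1")
})

test_that("variants on different chromosomes are never clumped together", {
  r <- makeRecords(c("rs1", "rs2"), beta = 0.1, se = 0.01,
                   pval = c(1e-20, 1e-9), pos = c(1e6, 1e6))
  r$chromosome <- c("1", "2")
  out <- clumpVariants(SummaryStats(r), ldInfo(
    data.frame(variant_a = character(), variant_b = character(),
               r2 = numeric())))
  expect_setequal(records(out)$variant_id, c("rs1", "rs2"))
})

test_that("clumping matches the brute-force oracle on dense instances", {
  set.seed(77)
  for (rep in 1:25) {
    n <- 10
    ids <- sprintf("rs%02d", sample(n))
    df <- makeRecords(ids, beta = 0.1, se = 0.01,
                      pval = runif(n, 1e-12, 1e-8),
                      pos = sort(sample(1e6:2e6, n)))
    m <- matrix(runif(n * n), n, n, dimnames = list(sort(ids), sort(ids)))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    got <- records(clumpVariants(SummaryStats(df), ldInfo(m),
                                 clumpKb = 10000, clumpR2 = 0.3))$variant_id
    want <- oracleClump(df, m, kb = 10000, r2max = 0.3)
    expect_equal(got, want)
  }
})

test_that("clumping is invariant to input row order", {
  set.seed(78)
  n <- 12
  ids <- sprintf("rs%02d", 1:n)
  df <- makeRecords(ids, beta = 0.1, se = 0.01,
                    pval = sample(c(1e-10, 1e-10, runif(n - 2, 1e-12, 1e-8))),
                    pos = sort(sample(1e6:1.05e6, n)))
  m <- matrix(runif(n * n, 0, 0.2), n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  a <- clumpVariants(SummaryStats(df), ldInfo(m), clumpR2 = 0.1)
  b <- clumpVariants(SummaryStats(df[sample(n), ]), ldInfo(m), clumpR2 = 0.1)
  expect_identical(records(a)$variant_id, records(b)$variant_id)
})

test_that("unknown LD within a window follows the configured policy", {
  ss <- makeStats(c("rs1", "rs2"), beta = 0.1, se = 0.01,
                  pval = c(1e-20, 1e-9), pos = c(1e6, 1.1e6))
  emptyLd <- ldInfo(data.frame(variant_a = character(),
                               variant_b = character(), r2 = numeric()))
  expect_equal(nVariants(clumpVariants(ss, emptyLd)), 1L)  # treat-as-linked
  expect_error(clumpVariants(ss, emptyLd, missingLd = "error"),
               class = "mrchain_missing_ld")
})

test_that("independent mode removes only same-position duplicates", {
  ss <- makeStats(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                  pval = c(1e-20, 1e-9, 1e-10), pos = c(1e6, 1e6, 1.2e6))
  out <- clumpVariants(ss, ldIndependent())
  expect_setequal(records(out)$variant_id, c("rs1", "rs3"))
})

test_that("selectInstruments composes the three filters with stage counts", {
  set.seed(79)
  # planted scenario: significant block, LD pairs, weak instruments
  nSig <- 120
  ids <- sprintf("rs%03d", seq_len(nSig + 30))
  beta <- c(rep(0.3, nSig - 4), rep(0.005, 4), rep(0.001, 30))
  se <- rep(0.002, nSig + 30)
  pval <- c(rep(1e-30, nSig), rep(0.5, 30))
  pos <- 1e6 + 2e7 * seq_along(ids)
  # 16 of the significant SNPs form 8 tight LD pairs
  pos[2 * (1:8)] <- pos[2 * (1:8) - 1] + 1e3
  ss <- makeStats(ids, beta = beta, se = se, pval = pval, pos = pos)
  pairs <- data.frame(variant_a = ids[2 * (1:8) - 1],
                      variant_b = ids[2 * (1:8)], r2 = 0.95)
  sel <- selectInstruments(ss, ldInfo(pairs), instrumentConfig())
  # oracle composition applied independently
  sig <- ids[pval < 5e-8]
  afterClump <- setdiff(sig, ids[2 * (1:8)])
  strong <- afterClump[beta[match(afterClump, ids)]^2 /
                       se[match(afterClump, ids)]^2 > 10]
  expect_setequal(records(sel)$variant_id, strong)
  st <- sel@meta$stages
  expect_equal(st$count, c(150, 120, 112, 108))
  expect_true(all(diff(st$count) <= 0))
})

test_that("an emptying stage raises a no-instruments error naming it", {
  weak <- makeStats(c("rs1", "rs2", "rs3"), beta = 0.001, se = 0.01,
                    pval = 1e-10)
  err <- expect_error(selectInstruments(weak, ldIndependent()),
                      class = "mrchain_no_instruments")
  expect_match(conditionMessage(err), "strength")
  insig <- makeStats("rs1", beta = 0.1, se = 0.01, pval = 0.5)
  err2 <- expect_error(selectInstruments(insig, ldIndependent()),
                       class = "mrchain_no_instruments")
  expect_match(conditionMessage(err2), "significance")
})

test_that("simulated planted instruments survive selection with high probability", {
  sim <- simulateUnivariable(simulationConfig(nSnps = 50L, nNullSnps = 950L,
                                              seed = 5L))
  sel <- selectInstruments(sim$exposure, sim$ld)
  kept <- records(sel)$variant_id
  planted <- sim$truth$instrumentIds
  expect_gte(length(intersect(kept, planted)), 48L)
  expect_lte(length(setdiff(kept, planted)), 2L)
})

test_that("LD round-trips through file formats", {
  pairs <- data.frame(variant_a = c("rs1", "rs2"), variant_b = c("rs2", "rs3"),
                      r2 = c(0.5, 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- readLdInfo(path)
  expect_equal(ld@mode, "pairs")
  expect_equal(nrow(ld@pairs), 2L)
  m <- matrix(c(1, .4, .4, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(id = rownames(m), m, check.names = FALSE), mpath,
              sep = "\t", quote = FALSE, row.names = FALSE)
  ld2 <- readLdInfo(mpath)
  expect_equal(ld2@pairs$r2, 0.4)
})
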
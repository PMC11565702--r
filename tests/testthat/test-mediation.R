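# BH-FDR, delta-method decomposition, mediator screening.

test_that("BH adjustment matches hand arithmetic and handles ties", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bhFDR(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bhFDR(c(0.1, 0)), class = "mrchain_config_error")
  expect_error(bhFDR(numeric()), class = "mrchain_config_error")
})

test_that("BH adjustment matches a brute-force step-up oracle on random vectors", {
  set.seed(501)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhFDR(p), oracleBH(p))
  }
})

test_that("q-values never fall below p and respect the BH partial order", {
  set.seed(502)
  p <- runif(30)
  q <- bhFDR(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("delta-method decomposition follows the product and ratio formulas", {
  m <- twoStepMediation(te = 1, teSe = 0.1, b1 = 0.5, b1Se = 0.1,
                        b2 = 0.4, b2Se = 0.2)
  expect_equal(m@ie, 0.2)
  expect_equal(m@ieSe, sqrt(0.0116))
  expect_equal(m@de, 0.8)
  expect_equal(m@proportion, 0.2)
  expect_equal(m@propSe,
               sqrt(0.0116 / 1 + 0.2^2 * 0.1^2 / 1))
  zero <- twoStepMediation(te = 0.3, teSe = 0.05, b1 = 0, b1Se = 0.1,
                           b2 = 0.4, b2Se = 0.2)
  expect_equal(zero@ie, 0)
  expect_equal(zero@de, 0.3)
})

test_that("identities DE + IE = TE and IE = b1*b2 hold over random inputs", {
  set.seed(503)
  for (rep in 1:50) {
    m <- twoStepMediation(te = rnorm(1), teSe = runif(1, 0.01, 1),
                          b1 = rnorm(1), b1Se = runif(1, 0.01, 1),
                          b2 = rnorm(1), b2Se = runif(1, 0.01, 1))
    expect_equal(m@de + m@ie, m@te, tolerance = 1e-15)
    expect_identical(m@ie, m@beta1 * m@beta2)
  }
})

test_that("the proportion is invariant under reciprocal rescaling of b1 and b2", {
  base <- twoStepMediation(te = 0.09, teSe = 0.02, b1 = -0.02, b1Se = 0.007,
                           b2 = -0.12, b2Se = 0.06)
  cc <- 5
  scaled <- twoStepMediation(te = 0.09, teSe = 0.02, b1 = -0.02 * cc,
                             b1Se = 0.007 * cc, b2 = -0.12 / cc,
                             b2Se = 0.06 / cc)
  expect_equal(scaled@ie, base@ie)
  expect_equal(scaled@proportion, base@proportion)
})

test_that("a zero total effect warns and leaves the proportion undefined", {
  expect_warning(
    m <- twoStepMediation(te = 0, teSe = 0.1, b1 = 0.5, b1Se = 0.1,
                          b2 = 0.4, b2Se = 0.2),
    class = "mrchain_undefined_proportion")
  expect_true(is.na(m@proportion))
  expect_equal(m@ie, 0.2)
  expect_equal(m@de, -0.2)
})

test_that("the in-study worked example reproduces the printed mediated share", {
  m <- twoStepMediation(te = log(1.092), teSe = 0.0206,
                        b1 = log(0.982), b1Se = 0.0070,
                        b2 = log(0.885), b2Se = 0.0598)
  expect_equal(100 * mediatedProportion(m), 2.52, tolerance = 0.01)
})

test_that("the screen recovers a true mediation chain end to end", {
  cfg <- simulationConfig(seed = 61L, mediationChain = mediationChain())
  sim <- simulateMediationChain(cfg)
  scr <- screenMediators(sim$exposure, list(sim$mediator), sim$outcome,
                         alpha = 1)
  expect_equal(scr$status, "mediator")
  expect_false(is.na(scr$proportion))
  expect_lt(abs(scr$proportion - sim$truth$proportion), 0.03)
  res <- attr(scr, "results")[[1]]
  expect_equal(res@de + res@ie, res@te, tolerance = 1e-15)
})

test_that("alpha = 1 passes every estimable row to step 2", {
  cfg <- simulationConfig(seed = 62L, nSnps = 60L,
                          mediationChain = mediationChain())
  panel <- simulateMetabolitePanel(cfg, nMediators = 6L, nTrue = 1L)
  scr <- screenMediators(panel$exposure, panel$mediators, panel$outcome,
                         alpha = 1)
  expect_true(all(!is.na(scr$step2_pval[!is.na(scr$step1_pval)])))
})

test_that("a mostly-null panel flags the planted mediator and respects FDR", {
  cfg <- simulationConfig(seed = 63L, mediationChain = mediationChain())
  panel <- simulateMetabolitePanel(cfg, nMediators = 10L, nTrue = 1L)
  scr <- screenMediators(panel$exposure, panel$mediators, panel$outcome,
                         alpha = 0.05)
  true <- panel$truth$trueMediators
  nullRows <- scr[!scr$mediator_id %in% true, ]
  expect_lte(sum(nullRows$status == "mediator"), 1L)
  trueRow <- scr[scr$mediator_id == true, ]
  if (trueRow$status == "mediator") {
    ci <- c(trueRow$prop_ci_low, trueRow$prop_ci_high)
    expect_gte(panel$truth$proportion[1], ci[1] - 0.05)
  }
})

test_that("a mediator sharing no variants with the screen is flagged, not fatal", {
  cfg <- simulationConfig(seed = 64L, mediationChain = mediationChain())
  sim <- simulateMediationChain(cfg)
  lonely <- makeStats(c("zz1", "zz2", "zz3"), beta = 0.3, se = 0.01,
                      pval = 1e-20, traitId = "lonely")
  scr <- screenMediators(sim$exposure, list(sim$mediator, lonely),
                         sim$outcome, alpha = 1)
  expect_equal(scr$status[scr$mediator_id == "lonely"], "no_instruments")
  expect_equal(scr$status[scr$mediator_id == "sim_mediator"], "mediator")
})
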
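# The five causal-effect estimators.

test_that("Wald ratio follows the ratio and first-order SE laws", {
  w <- waldRatio(0.5, 0.05, 0.1, 0.02)
  expect_equal(estimate(w), 0.2)
  expect_equal(stdError(w), 0.04)
  expect_equal(estimate(waldRatio(-0.5, 0.05, 0.1, 0.02)), -0.2)
  z <- waldRatio(1, 0.05, 0, 0.1)
  expect_equal(estimate(z), 0)
  expect_equal(pValue(z), 1)
  expect_error(waldRatio(0, 0.05, 0.1, 0.02),
               class = "mrchain_degenerate_instrument")
})

test_that("IVW fixed effects matches the closed form on two instruments", {
  h <- makeH(bx = c(1, 2), by = c(0.2, 0.4), sy = 0.1)
  est <- mrIVW(h, "fixed")
  expect_equal(estimate(est), 0.2)
  expect_equal(stdError(est), 1 / sqrt(500))
  expect_equal(mrExtra(est)$Q, 0)
  zero <- mrIVW(makeH(bx = c(1, 2), by = c(0, 0), sy = 0.1), "fixed")
  expect_equal(estimate(zero), 0)
  expect_error(mrIVW(makeH(1, 0.1)[1], "fixed"),
               class = "mrchain_insufficient_instruments")
})

test_that("IVW fixed effects equals the weighted mean of Wald ratios (200 random instances)", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(3:30, 1)
    bx <- rnorm(n, 0.2, 0.05)
    by <- rnorm(n, 0.02, 0.05)
    sy <- runif(n, 0.01, 0.2)
    h <- makeH(bx, by, sy = sy)
    expect_equal(estimate(mrIVW(h, "fixed")), oracleIvwFe(bx, by, sy),
                 tolerance = 1e-12)
  }
})

test_that("random-effects SE never falls below fixed and the auto gate records its branch", {
  set.seed(102)
  for (rep in 1:50) {
    n <- 20
    h <- makeH(rnorm(n, 0.2, 0.05), rnorm(n, 0.02, 0.08),
               sy = runif(n, 0.02, 0.1))
    fe <- mrIVW(h, "fixed")
    re <- mrIVW(h, "random")
    auto <- mrIVW(h, "auto")
    expect_gte(stdError(re), stdError(fe))
    het <- cochranQ(h)
    if (het@Q <= het@df) expect_equal(stdError(re), stdError(fe))
    expect_equal(mrExtra(auto)$model,
                 if (pValue(het) < 0.05) "random" else "fixed")
    expect_equal(estimate(auto), estimate(fe))  # point estimate unaffected
  }
})

test_that("Egger recovers exact affine structure", {
  h <- makeH(bx = c(1, 2, 3), by = c(0.2, 0.4, 0.6), sy = 0.05)
  e <- mrEgger(h)
  expect_equal(estimate(e), 0.2, tolerance = 1e-12)
  expect_equal(mrExtra(e)$intercept, 0, tolerance = 1e-12)
  h2 <- makeH(bx = c(1, 2, 3), by = c(0.25, 0.45, 0.65), sy = 0.05)
  e2 <- mrEgger(h2)
  expect_equal(estimate(e2), 0.2, tolerance = 1e-12)
  expect_equal(mrExtra(e2)$intercept, 0.05, tolerance = 1e-12)
  expect_error(mrEgger(makeH(c(1, 2), c(0.1, 0.2))),
               class = "mrchain_insufficient_instruments")
})

test_that("Egger is invariant to flipping any single instrument's orientation", {
  set.seed(103)
  n <- 10
  h <- makeH(rnorm(n, 0.2, 0.08), rnorm(n, 0.05, 0.05), sy = 0.05)
  base <- mrEgger(h)
  for (j in c(1, 4, n)) {
    bx <- h@betaExp; by <- h@betaOut
    bx[j] <- -bx[j]; by[j] <- -by[j]
    flipped <- mrEgger(makeH(bx, by, sx = h@seExp, sy = h@seOut))
    expect_equal(estimate(flipped), estimate(base), tolerance = 1e-12)
    expect_equal(mrExtra(flipped)$intercept, mrExtra(base)$intercept,
                 tolerance = 1e-12)
  }
})

test_that("weighted median interpolates the percentile construction", {
  h <- makeH(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.9), sy = 1)
  est <- mrWeightedMedian(h, nBoot = 50, seed = 1)
  expect_equal(estimate(est), 0.2)
  flat <- mrWeightedMedian(makeH(bx = rep(1, 4), by = rep(0.3, 4), sy = 1),
                           nBoot = 200, seed = 1)
  expect_equal(estimate(flat), 0.3)
  expect_lt(stdError(flat), 2)  # bootstrap noise only
})

test_that("weighted median with equal weights and odd n is the sample median", {
  set.seed(104)
  for (rep in 1:20) {
    n <- sample(c(5, 7, 9, 11), 1)
    by <- rnorm(n)
    h <- makeH(bx = rep(1, n), by = by, sy = 1)
    expect_equal(estimate(mrWeightedMedian(h, nBoot = 2, seed = 1)),
                 median(by))
  }
})

test_that("weighted mode finds the dominant cluster", {
  h <- makeH(bx = rep(1, 4), by = c(0.2, 0.2, 0.2, 0.9), sy = 1)
  est <- mrWeightedMode(h, nBoot = 50, seed = 2)
  expect_equal(estimate(est), 0.2, tolerance = 0.02)
  tight <- makeH(bx = rep(1, 5), by = 0.5 + rnorm(5, 0, 1e-4), sy = 1)
  expect_equal(estimate(mrWeightedMode(tight, nBoot = 50, seed = 2)), 0.5,
               tolerance = 0.01)
})

test_that("weighted mode argmax lands in the 60% cluster of a bimodal mix", {
  set.seed(105)
  by <- c(rnorm(30, 0.1, 0.01), rnorm(20, 0.6, 0.01))
  h <- makeH(bx = rep(1, 50), by = by, sy = 1)
  est <- mrWeightedMode(h, nBoot = 20, seed = 3)
  expect_lt(abs(estimate(est) - 0.1), 0.1)
  # dense-grid brute force agrees
  ratio <- by
  w <- rep(1 / 50, 50)
  bw <- 0.9 * mad(ratio) * 50^(-1 / 5)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 100000)
  dens <- sapply(ratio, function(r) dnorm(grid, r, bw)) %*% w
  expect_equal(estimate(est), grid[which.max(dens)], tolerance = 1e-3)
})

test_that("all estimators are equivariant under outcome scaling", {
  set.seed(106)
  n <- 12
  bx <- rnorm(n, 0.2, 0.05)
  by <- rnorm(n, 0.02, 0.03)
  sy <- runif(n, 0.02, 0.08)
  h1 <- makeH(bx, by, sx = 0.01, sy = sy)
  cc <- 3.7
  h2 <- makeH(bx, cc * by, sx = 0.01, sy = cc * sy)
  for (fn in list(function(h) mrIVW(h, "auto"),
                  mrEgger,
                  function(h) mrWeightedMedian(h, nBoot = 50, seed = 9),
                  function(h) mrWeightedMode(h, nBoot = 50, seed = 9))) {
    a <- fn(h1); b <- fn(h2)
    expect_equal(estimate(b), cc * estimate(a), tolerance = 1e-6)
    expect_equal(stdError(b), cc * stdError(a), tolerance = 1e-6)
  }
})

test_that("odds ratios are exact exponentials and CIs bracket estimates", {
  set.seed(107)
  h <- makeH(rnorm(8, 0.3, 0.05), rnorm(8, 0.03, 0.02), sy = 0.03)
  for (est in list(mrIVW(h), mrEgger(h),
                   mrWeightedMedian(h, nBoot = 20, seed = 1))) {
    expect_identical(oddsRatio(est), exp(estimate(est)))
    ci <- confInt(est)
    expect_lte(ci[1], estimate(est))
    expect_gte(ci[2], estimate(est))
  }
})
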
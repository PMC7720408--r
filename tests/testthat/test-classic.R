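test_that("2SLS is exact on noise-free unconfounded data", {
  cfg <- simConfig(overlapRate = 1, deltaTrue = 0, deltaOutcome = 0,
    sigmaTrue = 1e-9, uVarTrue = 1e-18, nPopulation = 200L, nStudy = 100L)
  d <- generatePopulation(cfg, seed = 601)
  est <- fit2sls(d)
  expect_equal(classicBeta(est), rep(0.3, 3), tolerance = 1e-6)
  expect_identical(est@method, "2SLS")
})

test_that("2SLS equals the closed-form projection sandwich", {
  d <- makeCompleteData(20, seed = 602)
  est <- fit2sls(d)
  oracle <- oracle2sls(instruments(d), exposures(d), outcome(d))
  expect_equal(classicBeta(est), oracle$coef, tolerance = 1e-10,
    ignore_attr = TRUE)
  expect_equal(est@se, oracle$se, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(est@ci[, 1], classicBeta(est) - 1.96 * est@se)
  expect_equal(est@ci[, 2], classicBeta(est) + 1.96 * est@se)
})

test_that("2SLS is consistent under confounding where OLS is biased", {
  n <- 1e5
  d <- makeCompleteData(n, seed = 603)
  est <- fit2sls(d)
  expect_lt(max(abs(classicBeta(est) - 0.3)), 0.01)
  ## OLS converges to beta + SigmaX^{-1} Cov(X, U) delta_Y instead
  D <- cbind(1, exposures(d))
  ols <- drop(solve(crossprod(D), crossprod(D, outcome(d))))[-1]
  vz <- 2 * 0.3 * 0.7; uv <- 0.01
  SigX <- matrix(uv, 3, 3)
  diag(SigX) <- 0.25 * vz + uv + 0.01
  SigX[3, 3] <- 2 * 0.25 * vz + uv + 0.01
  SigX[2, 3] <- SigX[3, 2] <- 0.25 * vz + uv
  bias <- drop(solve(SigX, rep(uv, 3))) * 1
  expect_equal(ols, 0.3 + bias, tolerance = 0.01, ignore_attr = TRUE)
  expect_gt(max(abs(ols - 0.3)), 3 * max(abs(classicBeta(est) - 0.3)))
})

test_that("summary statistics reproduce the loading pattern", {
  cfg <- simConfig(overlapRate = 0, deltaTrue = 0, deltaOutcome = 0,
    sigmaTrue = 1e-9, uVarTrue = 1e-18, nPopulation = 1000L, nStudy = 400L)
  d <- simulateDesign(cfg, seed = 604)
  st <- computeSummaryStats(d)
  expect_identical(c(st@nB, st@nC), c(400L, 400L))
  ## noise-free slopes: gamma follows the instrument-exposure graph. Where
  ## an exposure depends on its instrument alone the slope is exact; where
  ## other instruments contribute, finite-sample instrument correlation
  ## leaves O(1/sqrt(n)) residue
  expect_equal(st@gammaHat[1, 1], 0.5, tolerance = 1e-9)
  expect_equal(st@gammaHat[2, 2], 0.5, tolerance = 1e-9)
  expect_lt(abs(st@gammaHat[1, 2]), 0.05)
  expect_lt(abs(st@gammaHat[1, 3]), 0.05)
  expect_lt(abs(st@gammaHat[2, 3] - 0.5), 0.05)  # pleiotropic Z2
  expect_lt(abs(st@gammaHat[3, 3] - 0.5), 0.05)
})

test_that("summary-statistic slopes match an independent regression fit", {
  set.seed(605)
  Z <- matrix(rnorm(15), 5, 3)
  X <- matrix(rnorm(15), 5, 3)
  Y <- rnorm(5)
  d <- mrData(rbind(Z, Z), rbind(X, matrix(NA_real_, 5, 3)),
    c(rep(NA_real_, 5), Y), group = rep(c("B", "C"), each = 5))
  st <- computeSummaryStats(d)
  for (j in 1:3) {
    for (k in 1:3) {
      f <- stats::lm(X[, k] ~ Z[, j])
      expect_equal(st@gammaHat[j, k], unname(coef(f)[2]), tolerance = 1e-10)
      expect_equal(st@gammaSe[j, k],
        unname(sqrt(diag(vcov(f)))[2]), tolerance = 1e-10)
    }
    f <- stats::lm(Y ~ Z[, j])
    expect_equal(st@GammaHat[j], unname(coef(f)[2]), tolerance = 1e-10)
  }
})

test_that("outcome associations trace the causal paths", {
  ## plim Gamma_2 = alpha_2 beta_2 + alpha_3 beta_3 under independent Z
  cfg <- simConfig(overlapRate = 0, nPopulation = 2e5, nStudy = 9e4)
  d <- simulateDesign(cfg, seed = 606)
  st <- computeSummaryStats(d)
  expect_lt(abs(st@GammaHat[1] - 0.5 * 0.3), 0.01)
  expect_lt(abs(st@GammaHat[2] - (0.5 * 0.3 + 0.5 * 0.3)), 0.01)
  expect_lt(abs(st@GammaHat[3] - 0.5 * 0.3), 0.01)
})

test_that("IVW solves the weighted least-squares problem", {
  ## identity loadings pass the outcome associations straight through
  st <- new("SummaryStats", gammaHat = diag(3),
    gammaSe = matrix(0.1, 3, 3), GammaHat = rep(0.3, 3),
    GammaSe = rep(0.05, 3), nB = 10L, nC = 10L)
  expect_equal(classicBeta(fitIVW(st)), rep(0.3, 3))
  ## exactly identified: beta = gamma^{-1} Gamma whatever the weights
  set.seed(607)
  for (i in 1:5) {
    g <- matrix(rnorm(9, sd = 0.5), 3, 3) + diag(3)
    G <- rnorm(3)
    se <- runif(3, 0.02, 0.3)
    stR <- new("SummaryStats", gammaHat = g, gammaSe = matrix(0.1, 3, 3),
      GammaHat = G, GammaSe = se, nB = 10L, nC = 10L)
    expect_equal(classicBeta(fitIVW(stR)), drop(solve(g, G)),
      tolerance = 1e-10)
    ## rescaling all weights leaves the point estimate unchanged
    st2 <- stR; st2@GammaSe <- se * 7
    expect_equal(classicBeta(fitIVW(st2)), classicBeta(fitIVW(stR)),
      tolerance = 1e-12)
  }
  expect_error(fitIVW(new("SummaryStats",
    gammaHat = matrix(1, 3, 3), gammaSe = matrix(0.1, 3, 3),
    GammaHat = rep(0.3, 3), GammaSe = rep(0.05, 3), nB = 10L, nC = 10L)),
    "singular")
})

test_that("IVW is consistent on large two-sample data", {
  cfg <- simConfig(overlapRate = 0, nPopulation = 8.5e5, nStudy = 4e5)
  d <- simulateDesign(cfg, seed = 608)
  est <- fitIVW(computeSummaryStats(d))
  expect_lt(max(abs(classicBeta(est) - 0.3)), 0.01)
  expect_identical(est@method, "IVW")
})

test_that("the design-appropriate estimator switches at the overlap pattern", {
  d100 <- simulateDesign(simConfig(overlapRate = 1), seed = 609)
  expect_identical(classicForDesign(d100)@method, "2SLS")
  d80 <- simulateDesign(simConfig(overlapRate = 0.8), seed = 610)
  expect_identical(classicForDesign(d80)@method, "IVW")
  ## only the 80 + 80 non-overlapping rows feed the IVW stage
  st <- computeSummaryStats(d80)
  expect_identical(c(st@nB, st@nC), c(80L, 80L))
  d0 <- simulateDesign(simConfig(overlapRate = 0), seed = 611)
  expect_identical(classicForDesign(d0)@method, "IVW")
  ## a B-only design has no outcome side to regress on
  dB <- mrData(matrix(rnorm(30), 10, 3), matrix(rnorm(30), 10, 3),
    rep(NA_real_, 10), group = rep("B", 10))
  expect_error(classicForDesign(dB), "groups B and C")
})

test_that("classic intervals cover the null at their nominal rate", {
  nRep <- 100L
  cover2sls <- coverIVW <- matrix(NA, nRep, 3)
  cfg1 <- simConfig(overlapRate = 1, betaTrue = 0)
  cfg0 <- simConfig(overlapRate = 0, betaTrue = 0)
  for (r in seq_len(nRep)) {
    e1 <- fit2sls(simulateDesign(cfg1, seed = replicateSeed(700, 1, r)))
    cover2sls[r, ] <- e1@ci[, 1] <= 0 & 0 <= e1@ci[, 2]
    e0 <- classicForDesign(simulateDesign(cfg0, seed = replicateSeed(700, 2, r)))
    coverIVW[r, ] <- e0@ci[, 1] <= 0 & 0 <= e0@ci[, 2]
  }
  expect_true(all(colMeans(cover2sls) >= 0.90))
  expect_true(all(colMeans(coverIVW) >= 0.90))
})
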
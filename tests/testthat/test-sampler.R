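test_that("initialization starts at the stated values with one imputation", {
  cfg <- simConfig(overlapRate = 0.8)
  d <- simulateDesign(cfg, seed = 201)
  s <- initializeState(d, seed = 202)
  expect_identical(s@beta, rep(0, 3))
  expect_identical(s@alpha, rep(1, 4))
  expect_identical(s@delta, rep(0, 4))
  expect_identical(s@sigma, rep(1, 4))
  expect_length(s@Yimp, 80L)
  expect_identical(dim(s@Ximp), c(80L, 3L))
  s2 <- initializeState(d, seed = 202)
  expect_identical(s@Yimp, s2@Yimp)
  expect_identical(s@Ximp, s2@Ximp)
})

test_that("outcome imputation draws from the stated normal law", {
  ## degenerate scale: the draw collapses onto omega_Y + beta' x
  n <- 1e5
  X <- matrix(1, n, 3); Z <- matrix(0, n, 3)
  d <- mrData(Z, X, rep(NA_real_, n), group = rep("B", n))
  s <- new("ParameterState", beta = rep(0.3, 3), alpha = rep(0.5, 4),
    delta = rep(0, 4), omega = rep(0, 4), sigma = c(1, 1, 1, 1e-9),
    U = rep(0, n), Yimp = numeric(0), Ximp = matrix(0, 0, 3))
  set.seed(203)
  expect_equal(imputeY(s, d), rep(0.9, n), tolerance = 1e-6)
  ## moment check at a non-degenerate scale
  s@sigma[4] <- 0.4
  set.seed(204)
  y <- imputeY(s, d)
  expect_lt(abs(mean(y) - 0.9), 4 * 0.4 / sqrt(n))
  expect_lt(abs(sd(y) / 0.4 - 1), 0.02)
  ## empty group B is a no-op
  dA <- makeCompleteData(5, seed = 205)
  sA <- initializeState(dA)
  expect_identical(imputeY(sA, dA), numeric(0))
})

test_that("exposure imputation draws from the stated normal laws", {
  ## z = (2, 0, 2) with alpha = 0.5 maps to means (1, 0, 1)
  n <- 1e5
  Z <- matrix(rep(c(2, 0, 2), each = n), n, 3)
  d <- mrData(Z, matrix(NA_real_, n, 3), rnorm(n), group = rep("C", n))
  s <- new("ParameterState", beta = rep(0.3, 3), alpha = rep(0.5, 4),
    delta = rep(0, 4), omega = rep(0, 4), sigma = c(1e-9, 1e-9, 1e-9, 1),
    U = rep(0, n), Yimp = numeric(0), Ximp = matrix(0, 0, 3))
  set.seed(206)
  xs <- imputeX(s, d)
  expect_equal(xs[1, ], c(1, 0, 1), tolerance = 1e-6)
  s@sigma <- c(0.3, 0.3, 0.3, 1)
  set.seed(207)
  xs <- imputeX(s, d)
  for (k in 1:3) {
    expect_lt(abs(mean(xs[, k]) - c(1, 0, 1)[k]), 4 * 0.3 / sqrt(n))
    expect_lt(abs(sd(xs[, k]) / 0.3 - 1), 0.02)
  }
  ## empty group C is a no-op
  dA <- makeCompleteData(5, seed = 208)
  expect_identical(dim(imputeX(initializeState(dA), dA)), c(0L, 3L))
})

test_that("conditional exposure imputation matches its grid full conditional", {
  ## one C row, scalar check per exposure via numerical integration of
  ## prior(x) * lik(y | x) over a fine grid
  Z <- matrix(c(1, 2, 0), 1, 3)
  d <- mrData(Z, matrix(NA_real_, 1, 3), 0.9, group = "C")
  s <- new("ParameterState", beta = c(0.4, 0.2, 0.3), alpha = rep(0.5, 4),
    delta = c(0.5, 0.5, 0.5, 1), omega = rep(0, 4),
    sigma = c(0.2, 0.2, 0.2, 0.25), U = 0.3, Yimp = numeric(0),
    Ximp = matrix(0, 0, 3))
  set.seed(209)
  draws <- t(vapply(1:4000, function(i) imputeX(s, d, conditional = TRUE)[1, ],
    numeric(3)))
  ## brute force on a 3-d grid
  gx <- seq(-1.5, 2.5, length.out = 61)
  grid <- as.matrix(expand.grid(x1 = gx, x2 = gx, x3 = gx))
  pm <- c(0 + 0.5 * 1 + 0.5 * 0.3, 0 + 0.5 * 2 + 0.5 * 0.3,
    0 + 0.5 * 2 + 0.5 * 0 + 0.5 * 0.3)
  lp <- dnorm(grid[, 1], pm[1], 0.2, log = TRUE) +
    dnorm(grid[, 2], pm[2], 0.2, log = TRUE) +
    dnorm(grid[, 3], pm[3], 0.2, log = TRUE) +
    dnorm(0.9, grid %*% c(0.4, 0.2, 0.3) + 1 * 0.3, 0.25, log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  for (k in 1:3) {
    expect_lt(abs(mean(draws[, k]) - sum(w * grid[, k])), 0.02)
    expect_lt(abs(sd(draws[, k]) -
      sqrt(sum(w * grid[, k]^2) - sum(w * grid[, k])^2)), 0.02)
  }
})

test_that("coefficient draws center on the normal-equations solution", {
  ## flat-prior limit: the posterior mean of the outcome coefficients equals
  ## ordinary least squares of Y on (1, X)
  d <- makeCompleteData(50, seed = 210)
  D <- cbind(1, exposures(d))
  dr <- overlapMR:::drawCoef(D, outcome(d), sigma = 0.2,
    priorMean = rep(0, 4), priorPrec = rep(1e-12, 4))
  ols <- drop(solve(crossprod(D), crossprod(D, outcome(d))))
  expect_equal(dr$mean, ols, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the latent-confounder full conditional matches grid integration", {
  d <- makeCompleteData(1, seed = 211)
  s <- new("ParameterState", beta = c(0.3, 0.25, 0.35), alpha = rep(0.5, 4),
    delta = c(0.8, 0.6, 0.9, 1), omega = c(0.05, 0, -0.05, 0.1),
    sigma = c(0.2, 0.25, 0.15, 0.3), U = 0, Yimp = numeric(0),
    Ximp = matrix(0, 0, 3))
  fc <- overlapMR:::uFullConditional(s, d@Z, d@X, d@Y, priorSpec(),
    modelGraph())
  ## quadrature of prior(u) x all four residual likelihoods
  u <- seq(-3, 3, length.out = 20001)
  sl <- list(beta = s@beta, alpha = s@alpha, delta = s@delta,
    omega = s@omega, sigma = s@sigma)
  lp <- vapply(u, function(ui)
    oracleLogLik(sl, d@Z, d@X, d@Y, ui), numeric(1)) +
    dnorm(u, 0, sqrt(0.1), log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  expect_equal(fc$mean, sum(w * u), tolerance = 1e-6)
  expect_equal(fc$sd, sqrt(sum(w * u^2) - sum(w * u)^2), tolerance = 1e-5)
})

test_that("with no data the sweep samples the prior", {
  d0 <- mrData(matrix(0, 0, 3), matrix(0, 0, 3), numeric(0),
    group = character(0))
  cfg <- samplerConfig(nIter = 10, nWarmup = 1, mhStep = 0.8)
  set.seed(212)
  s <- initializeState(d0)
  nIt <- 6000L
  keep <- matrix(NA_real_, nIt, 3)
  for (t in seq_len(nIt)) {
    s <- updateParameters(s, d0, config = cfg)
    keep[t, ] <- c(s@alpha[1], s@beta[1], s@sigma[1])
  }
  keep <- keep[-(1:500), ]
  ## coefficient blocks are exact independent draws from their priors
  expect_gt(stats::ks.test(keep[, 1], pnorm, 1, 0.3)$p.value, 0.01)
  expect_gt(stats::ks.test(keep[, 2], pnorm, 0, 10)$p.value, 0.01)
  ## the Metropolis scale chain targets inv-gamma(3,2) on the sd:
  ## 1/sigma ~ Gamma(3, rate 2); thin the random walk before testing
  sig <- keep[seq(1, nrow(keep), by = 10), 3]
  expect_gt(stats::ks.test(1 / sig, pgamma, 3, 2)$p.value, 0.01)
  ## long-run moments of the instrument-strength prior
  expect_lt(abs(mean(keep[, 1]) - 1), 0.02)
  expect_lt(abs(sd(keep[, 1]) - 0.3), 0.02)
})

test_that("sampler marginals match brute-force grid posteriors", {
  ## two-row dataset; every block frozen except the intercepts and the
  ## outcome residual scale, so the outcome factor reduces to a 2-parameter
  ## model p(omega_Y, sigma_Y | y) that a dense grid can integrate
  Z <- matrix(c(1, 2, 0, 1, 2, 0), 2, 3)
  X <- matrix(c(0.5, 1.2, 0.2, 0.4, 1.0, 0.3), 2, 3)
  Y <- c(0.8, 1.1)
  d <- mrData(Z, X, Y, group = c("A", "A"))
  cfg <- samplerConfig(nIter = 42000, nWarmup = 2000, mhStep = 0.5,
    update = list(beta = FALSE, alpha = FALSE, delta = FALSE, u = FALSE,
      omega = TRUE, sigma = c(FALSE, FALSE, FALSE, TRUE)))
  fit <- runChain(d, config = cfg, seed = 213)
  draws <- posteriorDraws(fit)
  ## grid posterior of (omega_Y, sigma_Y): y_i ~ N(omega_Y, sigma_Y^2)
  ## (beta frozen at 0), omega_Y ~ N(0, 100), sigma_Y ~ inv-gamma(3, 2)
  gw <- seq(-4, 6, length.out = 401)
  gs <- seq(0.02, 6, length.out = 401)
  lp <- outer(gw, gs, function(w, s)
    dnorm(0.8, w, s, log = TRUE) + dnorm(1.1, w, s, log = TRUE) +
      dnorm(w, 0, 10, log = TRUE) + overlapMR:::logInvGamma(s, 3, 2))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  expect_lt(tvBinned(draws[, "omega4"], gw, rowSums(p)), 0.05)
  expect_lt(tvBinned(draws[, "sigma4"], gs, colSums(p)), 0.05)
  ## frozen blocks really stayed frozen
  expect_identical(unname(unique(draws[, "beta1"])), 0)
  expect_identical(unname(unique(draws[, "alpha2"])), 1)
})

test_that("equal-tailed credible intervals follow the percentile rule", {
  expect_equal(credibleInterval(1:100, 0.95),
    c(lower = 3.475, upper = 97.525))
  expect_equal(credibleInterval(rep(2.5, 10)), c(lower = 2.5, upper = 2.5))
  set.seed(214)
  ci <- credibleInterval(rnorm(1e6), 0.95)
  expect_equal(unname(ci), c(-1.96, 1.96), tolerance = 0.01)
  expect_error(credibleInterval(numeric(0)), "draws")
  expect_error(credibleInterval(1:10, 1.5), "level")
})

test_that("chains are reproducible and the engines agree", {
  cfg <- simConfig(overlapRate = 0.6, nPopulation = 500L, nStudy = 200L)
  d <- simulateDesign(cfg, seed = 215)
  sc <- samplerConfig(nIter = 1500, nWarmup = 500)
  f1 <- runChain(d, config = sc, seed = 216)
  f2 <- runChain(d, config = sc, seed = 216)
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))
  fR <- runChain(d, config = sc, seed = 216, engine = "R")
  sCpp <- posteriorSummary(f1); sR <- posteriorSummary(fR)
  expect_equal(sCpp$mean[1:3], sR$mean[1:3], tolerance = 0.015)
  expect_equal(sCpp$sd[1:3], sR$sd[1:3], tolerance = 0.2)
  expect_error(runChain(mrData(matrix(0, 0, 3), matrix(0, 0, 3),
    numeric(0), group = character(0))), "invalid dataset")
})

test_that("full overlap runs as a plain one-sample fit and recovers truth", {
  ## no imputation branch executes at 100% overlap
  cfg <- simConfig(overlapRate = 1)
  d <- simulateDesign(cfg, seed = 217)
  expect_identical(unname(groupSizes(d)["nB"]), 0L)
  s <- initializeState(d)
  expect_length(s@Yimp, 0L)
  expect_identical(nrow(s@Ximp), 0L)
  ## causal effects recovered: averaged over a few datasets the posterior
  ## means sit within the Monte-Carlo precision of the reference design
  sc <- samplerConfig(nIter = 1200, nWarmup = 400)
  est <- t(vapply(1:5, function(r) {
    dr <- simulateDesign(cfg, seed = 300 + r)
    posteriorSummary(runChain(dr, config = sc, seed = 300 + r))$mean[1:3]
  }, numeric(3)))
  expect_equal(unname(colMeans(est)), rep(0.3, 3), tolerance = 0.02)
})

test_that("split R-hat and effective size flag convergence sanely", {
  set.seed(218)
  x <- rnorm(4000); ch <- rep(1:2, each = 2000)
  expect_lt(abs(splitRhat(x, ch) - 1), 0.01)
  expect_gt(effectiveSize(x, ch), 2500)
  ## a drifting sequence is flagged
  bad <- cumsum(rnorm(4000, 0.05))
  expect_gt(splitRhat(bad, ch), 1.5)
  expect_lt(effectiveSize(bad, ch), 200)
  expect_true(is.na(splitRhat(rep(1, 100))))
})

test_that("precision rises and recovery holds across overlap rates", {
  rates <- c(1, 0.8, 0.6, 0.4, 0.2, 0)
  nRep <- 30L
  sc <- samplerConfig(nIter = 1200, nWarmup = 400)
  postMean <- array(NA_real_, c(length(rates), nRep, 3))
  postSd <- array(NA_real_, c(length(rates), nRep, 3))
  for (i in seq_along(rates)) {
    cfg <- simConfig(overlapRate = rates[i])
    for (r in seq_len(nRep)) {
      sd_ <- replicateSeed(400, i, r)
      d <- simulateDesign(cfg, seed = sd_)
      su <- posteriorSummary(runChain(d, config = sc, seed = sd_))
      postMean[i, r, ] <- su$mean[1:3]
      postSd[i, r, ] <- su$sd[1:3]
    }
  }
  ## unbiasedness of the replicate-averaged posterior mean at every rate
  for (i in seq_along(rates))
    expect_equal(unname(apply(postMean[i, , ], 2, mean)), rep(0.3, 3),
      tolerance = 0.03)
  ## posterior sd non-increasing in the overlap rate (rates run 1 -> 0 here,
  ## so the average posterior sd must be non-decreasing along the vector)
  for (k in 1:3) {
    prec <- apply(postSd[, , k], 1, mean)
    expect_true(all(diff(prec) > -0.003))
  }
})

test_that("credible intervals are calibrated under the generating model", {
  nRep <- 100L
  cfg <- simConfig(overlapRate = 0.6)
  sc <- samplerConfig(nIter = 1200, nWarmup = 400)
  covered <- matrix(NA, nRep, 3)
  for (r in seq_len(nRep)) {
    sd_ <- replicateSeed(500, 1, r)
    d <- simulateDesign(cfg, seed = sd_)
    su <- posteriorSummary(runChain(d, config = sc, seed = sd_))[1:3, ]
    covered[r, ] <- su$lower <= 0.3 & 0.3 <= su$upper
  }
  expect_true(all(colMeans(covered) >= 0.90))
})
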
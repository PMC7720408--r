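## Independent oracles and small fixture builders used across the suite.

## term-by-term log-likelihood written directly from the structural
## equations (independent of the package's vectorized implementation)
oracleLogLik <- function(state, Z, X, Y, U) {
  K <- ncol(X)
  lnorm <- function(x, m, s) -0.5 * log(2 * pi * s^2) - (x - m)^2 / (2 * s^2)
  tot <- 0
  for (i in seq_len(nrow(X))) {
    m1 <- state$omega[1] + state$alpha[1] * Z[i, 1] + state$delta[1] * U[i]
    m2 <- state$omega[2] + state$alpha[2] * Z[i, 2] + state$delta[2] * U[i]
    m3 <- state$omega[3] + state$alpha[3] * Z[i, 2] +
      state$alpha[4] * Z[i, 3] + state$delta[3] * U[i]
    mY <- state$omega[4] + sum(state$beta * X[i, ]) + state$delta[4] * U[i]
    tot <- tot + lnorm(X[i, 1], m1, state$sigma[1]) +
      lnorm(X[i, 2], m2, state$sigma[2]) +
      lnorm(X[i, 3], m3, state$sigma[3]) +
      lnorm(Y[i], mY, state$sigma[4])
  }
  unname(tot)
}

## closed-form 2SLS: beta = (X' P X)^-1 X' P y with P the projection onto
## the instrument block, plus the classical sandwich covariance
oracle2sls <- function(Z, X, Y) {
  Zd <- cbind(1, Z); Xd <- cbind(1, X)
  P <- Zd %*% solve(crossprod(Zd)) %*% t(Zd)
  bread <- solve(t(Xd) %*% P %*% Xd)
  coef <- bread %*% t(Xd) %*% P %*% Y
  res <- Y - Xd %*% coef
  s2 <- sum(res^2) / (nrow(Xd) - ncol(Xd))
  list(coef = drop(coef)[-1], se = sqrt(diag(s2 * bread))[-1])
}

## complete dataset with known structure for fixed-instance tests
makeCompleteData <- function(n, seed, alpha = 0.5, beta = 0.3, delta = 1,
                             sigma = 0.1, uVar = 0.01, maf = 0.3) {
  cfg <- simConfig(overlapRate = 1, alphaTrue = alpha, betaTrue = beta,
    deltaTrue = delta, sigmaTrue = sigma, uVarTrue = uVar, maf = maf,
    nPopulation = n, nStudy = min(n, 400L))
  generatePopulation(cfg, seed = seed)
}

## total variation distance between a binned sample and grid probabilities
tvBinned <- function(draws, gridX, gridP, nBins = 25L) {
  breaks <- seq(min(gridX), max(gridX), length.out = nBins + 1L)
  pGrid <- vapply(seq_len(nBins), function(b)
    sum(gridP[gridX >= breaks[b] & gridX < breaks[b + 1L]]), numeric(1))
  pGrid[nBins] <- pGrid[nBins] + sum(gridP[gridX == breaks[nBins + 1L]])
  h <- hist(pmin(pmax(draws, breaks[1L]), breaks[nBins + 1L]),
    breaks = breaks, plot = FALSE)
  pMcmc <- h$counts / length(draws)
  0.5 * sum(abs(pMcmc - pGrid / sum(pGrid)))
}
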
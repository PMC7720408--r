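## Markov chain scheme for the augmented model. Each iteration:
##   Step 2: impute missing outcomes (group B) and exposures (group C),
##   Step 3: merge imputed and observed cells into a complete dataset,
##   Step 4: one sweep of parameter updates targeting the complete-data
##           posterior (exact Gaussian full-conditional draws for all
##           regression coefficients and for each latent U_i; Metropolis or
##           conjugate updates for the residual scales).
## Given sigma the model is linear-Gaussian, so every coefficient update is
## an exact conditional draw; no tuning is required except the log-sigma
## random-walk step.

#' Initialize the sampler state
#'
#' Deterministic parameter start (causal effects and confounder effects at 0,
#' instrument strengths at their prior mean 1, intercepts 0, residual scales
#' 1, latent confounders 0) with the missing outcomes and exposures imputed
#' once from the structural equations at these initial values.
#'
#' @param data an [MRData-class].
#' @param priors a [PriorSpec-class].
#' @param seed optional integer seed (controls the initial imputation draw).
#' @param graph the [ModelGraph-class].
#'
#' @return A [ParameterState-class].
#' @export
initializeState <- function(data, priors = priorSpec(), seed = NULL,
                            graph = modelGraph()) {
  validObject(data)
  if (!is.null(seed)) set.seed(seed)
  K <- ncol(graph@loadings)
  n <- nIndividuals(data)
  state <- new("ParameterState",
    beta = rep(0, K),
    alpha = rep(priors@alphaMean, nAlpha(graph)),
    delta = rep(0, K + 1L),
    omega = rep(0, K + 1L),
    sigma = rep(1, K + 1L),
    U = rep(0, n),
    Yimp = numeric(0),
    Ximp = matrix(numeric(0), 0L, K))
  state@Yimp <- imputeY(state, data, graph = graph)
  state@Ximp <- imputeX(state, data, graph = graph)
  state
}

#' Impute missing outcomes for group-B rows
#'
#' One independent draw per group-B row from
#' \eqn{N(\omega_Y + \beta^\top x_i, \sigma_Y^2)} at the current parameters
#' (the latent confounder and the noise have mean zero and drop out of this
#' mean). With `conditional = TRUE` the current latent confounder value
#' enters the mean (\eqn{+\ \delta_Y U_i}), which makes the draw the exact
#' full conditional of the missing outcome.
#'
#' @param state a [ParameterState-class].
#' @param data an [MRData-class].
#' @param conditional include the latent-confounder term in the mean?
#' @param graph the [ModelGraph-class].
#'
#' @return Numeric vector of length `nB` (empty when there are no B rows).
#' @export
imputeY <- function(state, data, conditional = FALSE, graph = modelGraph()) {
  b <- data@group == "B"
  nB <- sum(b)
  if (nB == 0L) return(numeric(0))
  Xb <- data@X[b, , drop = FALSE]
  if (anyNA(Xb)) stop("group-B rows must have observed exposures")
  K <- length(state@beta)
  mu <- state@omega[K + 1L] + drop(Xb %*% state@beta)
  if (conditional) mu <- mu + state@delta[K + 1L] * state@U[b]
  rnorm(nB, mu, state@sigma[K + 1L])
}

#' Impute missing exposures for group-C rows
#'
#' With `conditional = FALSE`, each missing exposure is drawn from its
#' structural equation given the instruments only,
#' \eqn{X_k^* \sim N(\omega_k + \sum_j \alpha_{jk} z_j, \sigma_k^2)},
#' independent across rows and exposures; the observed outcome and the
#' latent confounder are deliberately not conditioned on. With
#' `conditional = TRUE` the draw is the exact joint full conditional of the
#' missing exposure vector, which also conditions on the observed outcome
#' (through the outcome equation) and the current latent confounder.
#'
#' @inheritParams imputeY
#' @return Numeric matrix `nC x K` (zero rows when there are no C rows).
#' @export
imputeX <- function(state, data, conditional = FALSE, graph = modelGraph()) {
  cc <- data@group == "C"
  nC <- sum(cc)
  K <- length(state@beta)
  if (nC == 0L) return(matrix(numeric(0), 0L, K))
  Zc <- data@Z[cc, , drop = FALSE]
  mu <- exposureMeans(Zc, graph, state@alpha, state@omega)
  sigK <- state@sigma[seq_len(K)]
  if (!conditional) {
    return(mu + matrix(rnorm(nC * K), nC, K) %*% diag(sigK, K))
  }
  yc <- data@Y[cc]
  if (anyNA(yc)) stop("group-C rows must have an observed outcome")
  uC <- state@U[cc]
  sigY <- state@sigma[K + 1L]
  priorMean <- mu + outer(uC, state@delta[seq_len(K)])
  ## full conditional: precision diag(1/sigma_k^2) + beta beta' / sigma_Y^2
  Q <- diag(1 / sigK^2, K) + tcrossprod(state@beta) / sigY^2
  S <- chol2inv(chol(Q))                       # posterior covariance
  resY <- yc - state@omega[K + 1L] - state@delta[K + 1L] * uC
  Bmat <- sweep(priorMean, 2L, sigK^2, "/") + outer(resY / sigY^2, state@beta)
  M <- Bmat %*% S
  M + matrix(rnorm(nC * K), nC, K) %*% chol(S)
}

## Exact draw from the posterior of a Gaussian linear regression with known
## noise sd and independent normal priors on the coefficients. Returns the
## posterior mean, the draw and the Cholesky factor of the precision.
drawCoef <- function(D, y, sigma, priorMean, priorPrec) {
  p <- ncol(D)
  Q <- crossprod(D) / sigma^2 + diag(priorPrec, p)
  b <- crossprod(D, y) / sigma^2 + priorPrec * priorMean
  R <- chol(Q)
  m <- backsolve(R, backsolve(R, b, transpose = TRUE))
  list(mean = drop(m), draw = drop(m) + backsolve(R, rnorm(p)),
    cholPrec = R)
}

## Full conditional of the latent confounders: normal with precision
## 1/uVar + sum_k delta_k^2 / sigma_k^2 (+ delta_Y^2 / sigma_Y^2) and mean
## proportional to the delta-weighted standardized residuals.
uFullConditional <- function(state, Z, Xc, Yc, priors, graph) {
  K <- length(state@beta)
  sig <- state@sigma
  del <- state@delta
  prec <- 1 / priors@uVar + sum(del^2 / sig^2)
  resX <- Xc - exposureMeans(Z, graph, state@alpha, state@omega)
  resY <- Yc - state@omega[K + 1L] - drop(Xc %*% state@beta)
  num <- drop(resX %*% (del[seq_len(K)] / sig[seq_len(K)]^2)) +
    del[K + 1L] * resY / sig[K + 1L]^2
  list(mean = num / prec, sd = sqrt(1 / prec))
}

## Metropolis update of one residual sd on the log scale, against the
## inverse-gamma prior on the sd. SS is the residual sum of squares, n the
## number of residuals.
mhSigma <- function(sigma, SS, n, priors, step) {
  logTarget <- function(s)
    -n * log(s) - SS / (2 * s^2) +
      logInvGamma(s, priors@sigmaShape, priors@sigmaRate) + log(s)
  prop <- sigma * exp(step * rnorm(1))
  if (log(runif(1)) < logTarget(prop) - logTarget(sigma)) prop else sigma
}

#' One sweep of parameter updates given completed data
#'
#' Updates, in order, the coefficients of each exposure equation (intercept,
#' instrument strengths and confounder effect jointly), the coefficients of
#' the outcome equation (intercept, causal effects and confounder effect
#' jointly), the latent confounder values, and the residual scales. All
#' coefficient and latent-confounder updates are exact Gaussian
#' full-conditional draws; residual scales follow
#' `config@sigmaUpdate`. Blocks disabled in `config@update` stay frozen.
#' The state's imputations are taken as data (the merge step); they are not
#' redrawn here.
#'
#' @param state a [ParameterState-class] whose imputations match `data`.
#' @param data an [MRData-class].
#' @param priors a [PriorSpec-class].
#' @param config a [SamplerConfig-class].
#' @param graph the [ModelGraph-class].
#'
#' @return The updated [ParameterState-class].
#' @export
updateParameters <- function(state, data, priors = priorSpec(),
                             config = samplerConfig(), graph = modelGraph()) {
  K <- ncol(graph@loadings)
  L <- graph@loadings
  n <- nIndividuals(data)
  xy <- completedXY(state, data)
  Xc <- xy$X; Yc <- xy$Y
  upd <- config@update
  sigmaFlags <- rep_len(upd$sigma, K + 1L)

  ## coefficient blocks: equation k has coefficients (omega_k, alpha_(k),
  ## delta_k); the outcome equation has (omega_Y, beta, delta_Y). alpha is
  ## ordered column-major over the loading edges, i.e. grouped by exposure.
  edgeOfExposure <- split(seq_len(nAlpha(graph)), rep(seq_len(K), colSums(L)))

  for (k in seq_len(K)) {
    instr <- which(L[, k])
    D <- cbind(rep(1, n), data@Z[, instr, drop = FALSE], state@U)
    coefs <- c(state@omega[k], state@alpha[edgeOfExposure[[k]]], state@delta[k])
    pm <- c(0, rep(priors@alphaMean, length(instr)), 0)
    pp <- c(1 / priors@omegaSd^2, rep(1 / priors@alphaSd^2, length(instr)),
      1 / priors@deltaSd^2)
    active <- c(upd$omega, rep(upd$alpha, length(instr)), upd$delta)
    if (any(active)) {
      yAdj <- Xc[, k] - D[, !active, drop = FALSE] %*% coefs[!active]
      dr <- drawCoef(D[, active, drop = FALSE], yAdj, state@sigma[k],
        pm[active], pp[active])
      coefs[active] <- dr$draw
      state@omega[k] <- coefs[1L]
      state@alpha[edgeOfExposure[[k]]] <- coefs[1L + seq_along(instr)]
      state@delta[k] <- coefs[length(coefs)]
    }
  }

  D <- cbind(rep(1, n), Xc, state@U)
  coefs <- c(state@omega[K + 1L], state@beta, state@delta[K + 1L])
  pm <- c(0, rep(priors@betaMean, K), 0)
  pp <- c(1 / priors@omegaSd^2, rep(1 / priors@betaSd^2, K),
    1 / priors@deltaSd^2)
  active <- c(upd$omega, rep(upd$beta, K), upd$delta)
  if (any(active)) {
    yAdj <- Yc - D[, !active, drop = FALSE] %*% coefs[!active]
    dr <- drawCoef(D[, active, drop = FALSE], yAdj, state@sigma[K + 1L],
      pm[active], pp[active])
    coefs[active] <- dr$draw
    state@omega[K + 1L] <- coefs[1L]
    state@beta <- coefs[1L + seq_len(K)]
    state@delta[K + 1L] <- coefs[K + 2L]
  }

  if (isTRUE(upd$u) && n > 0L) {
    fc <- uFullConditional(state, data@Z, Xc, Yc, priors, graph)
    state@U <- rnorm(n, fc$mean, fc$sd)
  }

  if (any(sigmaFlags)) {
    muX <- exposureMeans(data@Z, graph, state@alpha, state@omega) +
      outer(state@U, state@delta[seq_len(K)])
    muY <- state@omega[K + 1L] + drop(Xc %*% state@beta) +
      state@delta[K + 1L] * state@U
    for (k in seq_len(K + 1L)) {
      if (!sigmaFlags[k]) next
      SS <- if (k <= K) sum((Xc[, k] - muX[, k])^2) else sum((Yc - muY)^2)
      if (config@sigmaUpdate == "metropolis-sd") {
        state@sigma[k] <- mhSigma(state@sigma[k], SS, n, priors, config@mhStep)
      } else {
        v <- 1 / rgamma(1, priors@sigmaShape + n / 2,
          rate = priors@sigmaRate + SS / 2)
        state@sigma[k] <- sqrt(v)
      }
    }
  }

  if (any(!is.finite(state@beta)) || any(!is.finite(state@sigma)))
    stop("non-finite parameter values encountered in the update sweep")
  state
}

parNames <- function(graph) {
  K <- ncol(graph@loadings)
  c(paste0("beta", seq_len(K)), paste0("alpha", seq_len(nAlpha(graph))),
    paste0("delta", seq_len(K + 1L)), paste0("omega", seq_len(K + 1L)),
    paste0("sigma", seq_len(K + 1L)))
}

stateVector <- function(state) {
  c(state@beta, state@alpha, state@delta, state@omega, state@sigma)
}

#' Fit the Bayesian MR model by Markov chain Monte Carlo
#'
#' Runs the full scheme — impute missing outcomes and exposures, merge, one
#' parameter sweep — for `config@nIter` iterations per chain, discards
#' warmup, and summarizes the retained draws. When a group is empty its
#' imputation step is skipped; with fully complete data (100% overlap) the
#' algorithm is a plain one-sample Gibbs sampler.
#'
#' @param data an [MRData-class] with at least one row.
#' @param priors a [PriorSpec-class].
#' @param config a [SamplerConfig-class].
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param graph the [ModelGraph-class].
#' @param init optional [ParameterState-class] starting state (default
#'   [initializeState()]).
#' @param engine `"cpp"` (compiled inner loop, default) or `"R"` (reference
#'   implementation built from [imputeY()], [imputeX()] and
#'   [updateParameters()]). Runs with frozen parameter blocks always use the
#'   R engine.
#'
#' @return An [MRPosterior-class] with draws of all structural parameters
#'   (causal effects, instrument strengths, confounder effects, intercepts,
#'   residual scales), posterior means/sds, equal-tailed credible intervals,
#'   split R-hat and effective sample sizes.
#' @examples
#' cfg <- simConfig(overlapRate = 1, nPopulation = 300, nStudy = 150)
#' d <- simulateDesign(cfg, seed = 1)
#' fit <- runChain(d, config = samplerConfig(nIter = 400, nWarmup = 100),
#'   seed = 1)
#' posteriorSummary(fit)[1:3, ]
#' @export
runChain <- function(data, priors = priorSpec(), config = samplerConfig(),
                     seed = 1L, graph = modelGraph(), init = NULL,
                     engine = c("cpp", "R")) {
  validObject(data); validObject(config)
  engine <- match.arg(engine)
  if (nIndividuals(data) == 0L)
    stop("invalid dataset: no rows in any of groups A, B or C")
  conditional <- config@imputation == "conditional"
  allOn <- all(unlist(config@update))
  if (!allOn) engine <- "R"
  nKeep <- config@nIter - config@nWarmup
  pn <- parNames(graph)
  drawsAll <- vector("list", config@nChains)
  for (ch in seq_len(config@nChains)) {
    set.seed(as.integer(seed) + ch - 1L)
    state <- if (is.null(init)) {
      initializeState(data, priors, seed = NULL, graph = graph)
    } else init
    if (engine == "cpp") {
      draws <- .chainCpp(data@Z, data@X, data@Y,
        match(data@group, c("A", "B", "C")) - 1L,
        graph@loadings * 1L,
        list(betaMean = priors@betaMean, betaSd = priors@betaSd,
          alphaMean = priors@alphaMean, alphaSd = priors@alphaSd,
          deltaSd = priors@deltaSd, omegaSd = priors@omegaSd,
          uVar = priors@uVar, sigmaShape = priors@sigmaShape,
          sigmaRate = priors@sigmaRate),
        list(nIter = config@nIter, nWarmup = config@nWarmup,
          conditional = conditional,
          mhOnSd = config@sigmaUpdate == "metropolis-sd",
          mhStep = config@mhStep),
        list(beta = state@beta, alpha = state@alpha, delta = state@delta,
          omega = state@omega, sigma = state@sigma, U = state@U,
          Yimp = state@Yimp, Ximp = state@Ximp))
      colnames(draws) <- pn
    } else {
      draws <- matrix(NA_real_, nKeep, length(pn), dimnames = list(NULL, pn))
      for (t in seq_len(config@nIter)) {
        state@Yimp <- imputeY(state, data, conditional = conditional,
          graph = graph)
        state@Ximp <- imputeX(state, data, conditional = conditional,
          graph = graph)
        state <- updateParameters(state, data, priors, config, graph)
        if (t > config@nWarmup)
          draws[t - config@nWarmup, ] <- stateVector(state)
      }
    }
    drawsAll[[ch]] <- draws
  }
  draws <- do.call(rbind, drawsAll)
  chain <- rep(seq_len(config@nChains), each = nKeep)
  ci <- apply(draws, 2L, credibleInterval, level = config@credibleLevel)
  summ <- data.frame(parameter = pn,
    mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    lower = ci[1L, ], upper = ci[2L, ],
    rhat = vapply(seq_along(pn), function(j)
      splitRhat(draws[, j], chain), numeric(1)),
    ess = vapply(seq_along(pn), function(j)
      effectiveSize(draws[, j], chain), numeric(1)),
    row.names = NULL)
  new("MRPosterior", draws = draws, chain = as.integer(chain),
    summary = summ, level = config@credibleLevel, seed = as.integer(seed))
}

#' Equal-tailed credible interval
#'
#' Percentile interval with linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param draws numeric vector of at least 2 draws.
#' @param level interval level in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' credibleInterval(1:100, 0.95)  # 3.475 97.525
#' @export
credibleInterval <- function(draws, level = 0.95) {
  if (length(draws) < 2L) stop("need at least 2 draws")
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)")
  a <- (1 - level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so single-chain runs are still diagnosed).
#'
#' @param x draws of one parameter.
#' @param chain integer chain id per draw.
#' @return R-hat (>= 1 in expectation at convergence); `NA` for constant
#'   draws.
#' @export
splitRhat <- function(x, chain = rep(1L, length(x))) {
  parts <- splitChains(x, chain)
  m <- length(parts); n <- length(parts[[1L]])
  if (n < 2L) return(NA_real_)
  means <- vapply(parts, mean, numeric(1))
  vars <- vapply(parts, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= .Machine$double.eps * max(abs(means), 1))
    return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size using Geyer's initial
#' positive sequence on the split chains.
#'
#' @inheritParams splitRhat
#' @return Effective number of independent draws; `NA` for constant draws.
#' @export
effectiveSize <- function(x, chain = rep(1L, length(x))) {
  parts <- splitChains(x, chain)
  n <- length(parts[[1L]])
  if (n < 4L) return(NA_real_)
  if (stats::sd(x) <= .Machine$double.eps * max(abs(x), 1)) return(NA_real_)
  maxLag <- min(n - 2L, 200L)
  rhos <- sapply(parts, function(p)
    stats::acf(p, lag.max = maxLag, plot = FALSE,
      demean = TRUE)$acf[-1L, 1L, 1L])
  rho <- rowMeans(rhos)
  ## Geyer: sum consecutive-lag pairs while their sum stays positive
  pairSums <- rho[seq(1L, maxLag - 1L, by = 2L)] +
    rho[seq(2L, maxLag, by = 2L)]
  cut <- which(pairSums <= 0)
  nPairs <- if (length(cut)) cut[1L] - 1L else length(pairSums)
  tau <- 1 + 2 * (if (nPairs > 0) sum(pairSums[seq_len(nPairs)]) else 0)
  max(length(x) / max(tau, 1e-8), 1)
}

splitChains <- function(x, chain) {
  unlist(lapply(split(x, chain), function(xc) {
    h <- floor(length(xc) / 2L)
    list(xc[seq_len(h)], xc[h + seq_len(h)])
  }), recursive = FALSE)
}
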
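## Structural model density. Per individual i, conditionally on instruments
## and the latent confounder U_i:
##   X_ik | Z_i, U_i ~ N(omega_k + sum_j alpha_jk Z_ij + delta_k U_i, sigma_k^2)
##   Y_i | X_i, U_i  ~ N(omega_Y + beta' X_i + delta_Y U_i, sigma_Y^2)
## with U_i ~ N(0, uVar). All noise terms independent.

## Accept either a ParameterState or a plain named list (so that invalid
## regions of parameter space, e.g. sigma <= 0, can still be scored).
stateFields <- function(state) {
  if (is(state, "ParameterState"))
    list(beta = state@beta, alpha = state@alpha, delta = state@delta,
      omega = state@omega, sigma = state@sigma, U = state@U,
      Yimp = state@Yimp, Ximp = state@Ximp)
  else state
}

## Substitute the state's imputations into the dataset's missing cells.
completedXY <- function(state, data) {
  s <- stateFields(state)
  X <- data@X; Y <- data@Y
  b <- data@group == "B"; cc <- data@group == "C"
  if (any(b)) Y[b] <- s$Yimp
  if (any(cc)) X[cc, ] <- s$Ximp
  if (anyNA(X) || anyNA(Y))
    stop("missing cells remain after substituting imputations")
  list(X = X, Y = Y)
}

#' Complete-data log-likelihood of the structural model
#'
#' Evaluates the joint log density of all exposures and outcomes (observed
#' cells plus the state's imputations) given instruments, latent confounder
#' values and parameters. The likelihood factorizes over individuals and over
#' the K exposure equations plus the outcome equation.
#'
#' @param state a [ParameterState-class] (or a plain named list with the same
#'   fields).
#' @param data an [MRData-class].
#' @param graph the [ModelGraph-class] (default [modelGraph()]).
#'
#' @return A single finite number for finite inputs.
#' @export
completeDataLogLik <- function(state, data, graph = modelGraph()) {
  s <- stateFields(state)
  n <- nIndividuals(data)
  K <- ncol(graph@loadings)
  if (length(s$U) != n)
    stop("length(U) must equal the number of data rows")
  if (length(s$beta) != K || length(s$sigma) != K + 1L)
    stop("parameter dimensions do not match the model graph")
  if (n == 0L) return(0)
  xy <- completedXY(s, data)
  muX <- exposureMeans(data@Z, graph, s$alpha, s$omega) +
    outer(s$U, s$delta[seq_len(K)])
  ll <- sum(stats::dnorm(xy$X, muX,
    rep(s$sigma[seq_len(K)], each = n), log = TRUE))
  muY <- s$omega[K + 1L] + drop(xy$X %*% s$beta) + s$delta[K + 1L] * s$U
  ll + sum(stats::dnorm(xy$Y, muY, s$sigma[K + 1L], log = TRUE))
}

## Inverse-gamma log density (shape a, rate b) evaluated at x > 0:
## log f(x) = a log b - log Gamma(a) - (a + 1) log x - b / x
logInvGamma <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

#' Log prior density of a parameter state
#'
#' Sum of the log prior densities of all unknowns, including the latent
#' confounder values U under their fixed N(0, uVar) law. States with any
#' non-positive residual scale score `-Inf` (rejected), not an error.
#'
#' @inheritParams completeDataLogLik
#' @param priors a [PriorSpec-class].
#'
#' @return A single number, possibly `-Inf`.
#' @export
logPrior <- function(state, priors = priorSpec()) {
  s <- stateFields(state)
  if (any(!is.finite(s$sigma)) || any(s$sigma <= 0)) return(-Inf)
  sum(stats::dnorm(s$beta, priors@betaMean, priors@betaSd, log = TRUE)) +
    sum(stats::dnorm(s$alpha, priors@alphaMean, priors@alphaSd, log = TRUE)) +
    sum(stats::dnorm(s$delta, 0, priors@deltaSd, log = TRUE)) +
    sum(stats::dnorm(s$omega, 0, priors@omegaSd, log = TRUE)) +
    sum(logInvGamma(s$sigma, priors@sigmaShape, priors@sigmaRate)) +
    sum(stats::dnorm(s$U, 0, sqrt(priors@uVar), log = TRUE))
}

#' Unnormalized log posterior of a parameter state
#'
#' `logPrior(state, priors) + completeDataLogLik(state, data, graph)`; the
#' quantity targeted by the sampler for complete (or completed) data.
#'
#' @inheritParams logPrior
#' @inheritParams completeDataLogLik
#' @return A single number, possibly `-Inf`.
#' @export
logPosteriorUnnorm <- function(state, data, priors = priorSpec(),
                               graph = modelGraph()) {
  lp <- logPrior(state, priors)
  if (!is.finite(lp)) return(lp)
  lp + completeDataLogLik(state, data, graph)
}
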
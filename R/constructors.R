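#' Construct an instrument-exposure loading graph
#'
#' @param loadings logical matrix (instruments in rows, exposures in columns);
#'   `NULL` gives the default three-instrument, three-exposure graph with a
#'   pleiotropic second instrument (four free strengths).
#'
#' @return A [ModelGraph-class] object.
#' @examples
#' g <- modelGraph()
#' nAlpha(g)  # 4
#' @export
modelGraph <- function(loadings = NULL) {
  if (is.null(loadings)) {
    loadings <- matrix(FALSE, 3L, 3L,
      dimnames = list(c("Z1", "Z2", "Z3"), c("X1", "X2", "X3")))
    loadings[1L, 1L] <- TRUE   # Z1 -> X1
    loadings[2L, 2L] <- TRUE   # Z2 -> X2
    loadings[2L, 3L] <- TRUE   # Z2 -> X3 (pleiotropy)
    loadings[3L, 3L] <- TRUE   # Z3 -> X3
  }
  new("ModelGraph", loadings = loadings)
}

#' Number of free instrument-strength parameters of a graph
#'
#' @param graph a [ModelGraph-class].
#' @return Integer count of loading edges.
#' @export
nAlpha <- function(graph) sum(graph@loadings)

#' Assemble an individual-level MR dataset
#'
#' @param Z instrument matrix (no missing values).
#' @param X exposure matrix; may contain `NA` rows (group C).
#' @param Y outcome vector; may contain `NA` (group B).
#' @param group optional character vector of `"A"`, `"B"`, `"C"`; derived
#'   from the missingness pattern when omitted.
#'
#' @return An [MRData-class] object (validated).
#' @export
mrData <- function(Z, X, Y, group = NULL) {
  Z <- as.matrix(Z); X <- as.matrix(X); Y <- as.numeric(Y)
  if (is.null(group)) {
    yMiss <- is.na(Y)
    xMiss <- rowSums(is.na(X)) > 0L
    group <- ifelse(yMiss, "B", ifelse(xMiss, "C", "A"))
  }
  new("MRData", Z = Z, X = X, Y = Y, group = as.character(group))
}

#' Specify one synthetic-data generating condition
#'
#' Defaults reproduce the reference simulation design: a population of 1000
#' individuals, two association studies of 400 each, strong instruments
#' (\eqn{\alpha = 0.5}), strong confounding of the exposures
#' (\eqn{\delta_{1:3} = 1}) with the confounder-outcome effect fixed at
#' \eqn{\delta_4 = 1}, causal effects \eqn{\beta = 0.3}, binomial dosage
#' instruments with allele frequency 0.3, zero intercepts and residual
#' standard deviations of 0.1.
#'
#' @param overlapRate fraction of each study shared by both studies, in
#'   `[0, 1]`.
#' @param alphaTrue true instrument strengths (length [nAlpha()] of `graph`),
#'   or a single value recycled.
#' @param betaTrue true causal effects (length = number of exposures), or a
#'   single value recycled.
#' @param deltaTrue true confounder effects on the exposures (recycled), the
#'   confounder-outcome effect being given by `deltaOutcome`.
#' @param deltaOutcome confounder effect on the outcome (default 1).
#' @param omegaTrue true intercepts, exposures then outcome (recycled).
#' @param sigmaTrue true residual standard deviations, exposures then outcome
#'   (recycled).
#' @param uVarTrue variance of the latent confounder draw (default 0.01; see
#'   the methods vignette for the calibration of this noise scale against
#'   the closed-form 2SLS sampling precision of the reference design).
#' @param nPopulation,nStudy population size and per-study sample size.
#' @param maf allele frequency for binomial dosage instruments.
#' @param zDist `"binomial"` or `"normal"` instrument distribution.
#' @param graph a [ModelGraph-class]; default [modelGraph()].
#'
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(overlapRate = 0.8)
#' computeSplitSizes(0.8, 400)
#' @export
simConfig <- function(overlapRate = 1, alphaTrue = 0.5, betaTrue = 0.3,
                      deltaTrue = 1, deltaOutcome = 1, omegaTrue = 0,
                      sigmaTrue = 0.1, uVarTrue = 0.01,
                      nPopulation = 1000L, nStudy = 400L,
                      maf = 0.3, zDist = c("binomial", "normal"),
                      graph = modelGraph()) {
  zDist <- match.arg(zDist)
  K <- ncol(graph@loadings)
  new("SimulationConfig",
    overlapRate = as.numeric(overlapRate),
    alphaTrue = rep_len(as.numeric(alphaTrue), nAlpha(graph)),
    betaTrue = rep_len(as.numeric(betaTrue), K),
    deltaTrue = c(rep_len(as.numeric(deltaTrue), K), as.numeric(deltaOutcome)),
    omegaTrue = rep_len(as.numeric(omegaTrue), K + 1L),
    sigmaTrue = rep_len(as.numeric(sigmaTrue), K + 1L),
    uVarTrue = as.numeric(uVarTrue),
    nPopulation = as.integer(nPopulation), nStudy = as.integer(nStudy),
    maf = as.numeric(maf), zDist = zDist, graph = graph)
}

#' Specify the priors of the structural model
#'
#' @param betaMean,betaSd normal prior on each causal effect (default
#'   mean 0, sd 10).
#' @param alphaMean,alphaSd normal prior on each instrument strength (default
#'   mean 1, sd 0.3).
#' @param deltaSd,omegaSd sd of the zero-mean normal priors on confounder
#'   effects and intercepts (default 10).
#' @param uVar prior variance of the latent confounder (default 0.1).
#' @param sigmaShape,sigmaRate inverse-gamma prior on each residual scale
#'   (default shape 3, rate 2).
#'
#' @return A [PriorSpec-class] object.
#' @export
priorSpec <- function(betaMean = 0, betaSd = 10, alphaMean = 1, alphaSd = 0.3,
                      deltaSd = 10, omegaSd = 10, uVar = 0.1,
                      sigmaShape = 3, sigmaRate = 2) {
  new("PriorSpec", betaMean = betaMean, betaSd = betaSd,
    alphaMean = alphaMean, alphaSd = alphaSd, deltaSd = deltaSd,
    omegaSd = omegaSd, uVar = uVar, sigmaShape = sigmaShape,
    sigmaRate = sigmaRate)
}

#' Sampler settings
#'
#' @param nIter,nWarmup,nChains iterations, warmup and chain count.
#' @param sigmaUpdate `"metropolis-sd"` (default; inverse-gamma prior on the
#'   residual *standard deviation*, updated by random-walk Metropolis on the
#'   log scale) or `"conjugate-variance"` (inverse-gamma on the *variance*,
#'   exact conjugate draw).
#' @param imputation `"conditional"` (default) draws missing outcomes and
#'   exposures from their full conditional distributions, which include the
#'   latent confounder and, for missing exposures, the observed outcome;
#'   `"marginal"` draws them from the bare structural equations at the
#'   current parameters.
#' @param credibleLevel credible-interval level (default 0.95).
#' @param mhStep random-walk step on the log residual scale.
#' @param update named list of logical block flags (`beta`, `alpha`, `delta`,
#'   `omega`, `u`, and length-4 `sigma`); missing entries default to `TRUE`.
#'   Frozen blocks keep their initial values, which is useful for
#'   conditional-posterior diagnostics.
#'
#' @return A [SamplerConfig-class] object.
#' @export
samplerConfig <- function(nIter = 3000L, nWarmup = 1000L, nChains = 1L,
                          sigmaUpdate = c("metropolis-sd", "conjugate-variance"),
                          imputation = c("conditional", "marginal"),
                          credibleLevel = 0.95, mhStep = 0.1,
                          update = list()) {
  sigmaUpdate <- match.arg(sigmaUpdate)
  imputation <- match.arg(imputation)
  full <- list(beta = TRUE, alpha = TRUE, delta = TRUE, omega = TRUE,
    u = TRUE, sigma = rep(TRUE, 4L))
  full[names(update)] <- update
  full$sigma <- rep_len(as.logical(full$sigma), 4L)
  new("SamplerConfig", nIter = as.integer(nIter), nWarmup = as.integer(nWarmup),
    nChains = as.integer(nChains), sigmaUpdate = sigmaUpdate,
    imputation = imputation, credibleLevel = credibleLevel,
    mhStep = mhStep, update = full)
}
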
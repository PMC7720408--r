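#' @import methods
NULL

#' Instrument-to-exposure loading structure
#'
#' A `ModelGraph` records which instrument is allowed a direct effect on which
#' exposure. Rows index instruments, columns index exposures; entry
#' \eqn{(j,k)} is `TRUE` when instrument \eqn{Z_j} loads on exposure
#' \eqn{X_k}. Each `TRUE` entry corresponds to one free instrument-strength
#' parameter \eqn{\alpha}; parameters are ordered column-major (by exposure,
#' then instrument within exposure).
#'
#' The default graph has three instruments and three exposures with
#' \eqn{Z_1 \to X_1}, \eqn{Z_2 \to X_2}, \eqn{Z_2 \to X_3} and
#' \eqn{Z_3 \to X_3}, i.e. four free strengths
#' \eqn{\alpha_1, \ldots, \alpha_4}. \eqn{Z_2} is horizontally pleiotropic:
#' it affects the outcome through both \eqn{X_2} and \eqn{X_3}.
#'
#' @slot loadings logical matrix, instruments in rows, exposures in columns.
#'
#' @seealso [modelGraph()]
#' @export
setClass("ModelGraph", representation(loadings = "matrix"))

setValidity("ModelGraph", function(object) {
  L <- object@loadings
  if (!is.logical(L) || anyNA(L))
    return("'loadings' must be a logical matrix without NA")
  if (nrow(L) < 1L || ncol(L) < 1L)
    return("'loadings' must have at least one instrument and one exposure")
  if (any(rowSums(L) == 0L))
    return("every instrument must load on at least one exposure")
  if (any(colSums(L) == 0L))
    return("every exposure must have at least one instrument")
  TRUE
})

#' Individual-level data for overlapping-sample Mendelian randomization
#'
#' One row per individual with instruments `Z` (always observed), exposures
#' `X` and outcome `Y`, plus a group label recording the missingness pattern:
#' group `"A"` rows observe everything, group `"B"` rows observe `(Z, X)` only
#' (outcome missing), group `"C"` rows observe `(Z, Y)` only (exposures
#' missing). `A` together with `B` is the instrument-exposure study and `A`
#' together with `C` the instrument-outcome study; the two studies overlap in
#' `A`.
#'
#' @slot Z numeric matrix of instrument values (e.g. genotype dosages), never
#'   missing.
#' @slot X numeric matrix of exposures; `NA` on group-C rows.
#' @slot Y numeric outcome vector; `NA` on group-B rows.
#' @slot group character vector of `"A"`, `"B"`, `"C"`.
#'
#' @seealso [mrData()], [generatePopulation()], [splitIntoABC()]
#' @export
setClass("MRData",
  representation(Z = "matrix", X = "matrix", Y = "numeric", group = "character"))

setValidity("MRData", function(object) {
  n <- nrow(object@Z)
  if (nrow(object@X) != n || length(object@Y) != n || length(object@group) != n)
    return("Z, X, Y and group must agree in number of rows")
  if (anyNA(object@Z))
    return("instruments Z must not contain missing values")
  if (!all(object@group %in% c("A", "B", "C")))
    return("group labels must be 'A', 'B' or 'C'")
  a <- object@group == "A"; b <- object@group == "B"; cc <- object@group == "C"
  if (anyNA(object@X[a | b, , drop = FALSE]))
    return("groups A and B must have fully observed exposures X")
  if (anyNA(object@Y[a | cc]))
    return("groups A and C must have an observed outcome Y")
  if (any(!is.na(object@Y[b])))
    return("group B rows must have missing outcome Y")
  if (any(!is.na(object@X[cc, , drop = FALSE])))
    return("group C rows must have all exposures X missing")
  TRUE
})

#' Configuration of one synthetic-data generating condition
#'
#' Holds the true parameter values and design constants of one simulation
#' condition: the structural model truth (`alphaTrue`, `betaTrue`,
#' `deltaTrue`, `omegaTrue`, `sigmaTrue`), the population and study sizes, the
#' overlap rate of the two association studies, and how instruments are
#' generated.
#'
#' @slot overlapRate fraction of the study size shared by the two studies.
#' @slot alphaTrue true instrument strengths, one per loading edge.
#' @slot betaTrue true causal effects of the exposures on the outcome.
#' @slot deltaTrue true confounder effects (on each exposure, then on the
#'   outcome; the last element is fixed at 1 in the reference design).
#' @slot omegaTrue true intercepts (exposures, then outcome).
#' @slot sigmaTrue true residual standard deviations (exposures, then
#'   outcome).
#' @slot uVarTrue variance of the latent confounder draw. The default 0.01
#'   is calibrated so that the closed-form 2SLS sampling sd of the reference
#'   design (n = 400, strong instruments) matches the precision of the
#'   classic-MR benchmark this generator is meant to emulate.
#' @slot nPopulation size of the fully observed source population.
#' @slot nStudy size of each of the two association studies.
#' @slot maf allele frequency used when instruments are binomial dosages.
#' @slot zDist `"binomial"` (dosage `Binomial(2, maf)`) or `"normal"`
#'   (standard normal).
#' @slot graph the [ModelGraph-class] loading structure.
#'
#' @seealso [simConfig()]
#' @export
setClass("SimulationConfig",
  representation(overlapRate = "numeric", alphaTrue = "numeric",
    betaTrue = "numeric", deltaTrue = "numeric", omegaTrue = "numeric",
    sigmaTrue = "numeric", uVarTrue = "numeric", nPopulation = "integer",
    nStudy = "integer", maf = "numeric", zDist = "character",
    graph = "ModelGraph"))

setValidity("SimulationConfig", function(object) {
  L <- object@graph@loadings
  K <- ncol(L)
  if (length(object@overlapRate) != 1L || is.na(object@overlapRate) ||
      object@overlapRate < 0 || object@overlapRate > 1)
    return("overlapRate must be a single value in [0, 1]")
  if (length(object@alphaTrue) != sum(L))
    return(sprintf("alphaTrue must have one value per loading edge (%d)", sum(L)))
  if (length(object@betaTrue) != K)
    return(sprintf("betaTrue must have length %d", K))
  if (length(object@deltaTrue) != K + 1L)
    return(sprintf("deltaTrue must have length %d (exposures then outcome)", K + 1L))
  if (length(object@omegaTrue) != K + 1L || length(object@sigmaTrue) != K + 1L)
    return(sprintf("omegaTrue and sigmaTrue must have length %d", K + 1L))
  if (any(object@sigmaTrue <= 0))
    return("all sigmaTrue must be > 0")
  if (length(object@uVarTrue) != 1L || object@uVarTrue <= 0)
    return("uVarTrue must be a single positive variance")
  if (object@nPopulation < 1L || object@nStudy < 1L)
    return("nPopulation and nStudy must be positive")
  if (object@nStudy > object@nPopulation)
    return("nStudy cannot exceed nPopulation")
  if (object@maf <= 0 || object@maf >= 1)
    return("maf must lie strictly between 0 and 1")
  if (!object@zDist %in% c("binomial", "normal"))
    return("zDist must be 'binomial' or 'normal'")
  TRUE
})

#' Prior specification for the structural model
#'
#' Independent normal priors on the causal effects \eqn{\beta} (mean 0, sd
#' 10), on the instrument strengths \eqn{\alpha} (mean 1, sd 0.3) and on the
#' confounder effects \eqn{\delta} and intercepts \eqn{\omega} (mean 0, sd
#' 10); an inverse-gamma prior (shape 3, scale 2) on each residual standard
#' deviation \eqn{\sigma}; and a fixed normal law with mean 0 and *variance*
#' `uVar` on the latent per-individual confounder U.
#'
#' @slot betaMean,betaSd normal prior on each causal effect.
#' @slot alphaMean,alphaSd normal prior on each instrument strength.
#' @slot deltaSd,omegaSd sd of the zero-mean normal priors on confounder
#'   effects and intercepts.
#' @slot uVar prior variance of the latent confounder U.
#' @slot sigmaShape,sigmaRate inverse-gamma parameters for the residual
#'   scales.
#'
#' @seealso [priorSpec()]
#' @export
setClass("PriorSpec",
  representation(betaMean = "numeric", betaSd = "numeric",
    alphaMean = "numeric", alphaSd = "numeric",
    deltaSd = "numeric", omegaSd = "numeric", uVar = "numeric",
    sigmaShape = "numeric", sigmaRate = "numeric"))

setValidity("PriorSpec", function(object) {
  pos <- c(betaSd = object@betaSd, alphaSd = object@alphaSd,
    deltaSd = object@deltaSd, omegaSd = object@omegaSd, uVar = object@uVar,
    sigmaShape = object@sigmaShape, sigmaRate = object@sigmaRate)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("all prior scale/shape parameters must be positive and finite")
  TRUE
})

#' Markov chain sampler settings
#'
#' @slot nIter total iterations per chain.
#' @slot nWarmup iterations discarded as warmup.
#' @slot nChains number of independent chains.
#' @slot sigmaUpdate `"metropolis-sd"` (random-walk Metropolis on
#'   \eqn{\log\sigma} against the inverse-gamma prior on the standard
#'   deviation) or `"conjugate-variance"` (exact inverse-gamma draw, placing
#'   the prior on the variance instead).
#' @slot imputation `"marginal"` imputes missing outcomes/exposures from their
#'   structural equations given the current parameters only (omitting the
#'   latent confounder and, for exposures, the observed outcome);
#'   `"conditional"` draws them from their full conditionals.
#' @slot credibleLevel level of the equal-tailed credible intervals.
#' @slot mhStep random-walk step size on \eqn{\log\sigma}.
#' @slot update named list of logical flags enabling the update of each
#'   parameter block (`beta`, `alpha`, `delta`, `omega`, `u`, and a length-4
#'   logical `sigma`); disabled blocks stay frozen at their initial values.
#'
#' @seealso [samplerConfig()], [runChain()]
#' @export
setClass("SamplerConfig",
  representation(nIter = "integer", nWarmup = "integer", nChains = "integer",
    sigmaUpdate = "character", imputation = "character",
    credibleLevel = "numeric", mhStep = "numeric", update = "list"))

setValidity("SamplerConfig", function(object) {
  if (object@nIter < 2L || object@nWarmup < 0L || object@nWarmup >= object@nIter)
    return("need 0 <= nWarmup < nIter")
  if (object@nChains < 1L) return("nChains must be >= 1")
  if (!object@sigmaUpdate %in% c("metropolis-sd", "conjugate-variance"))
    return("sigmaUpdate must be 'metropolis-sd' or 'conjugate-variance'")
  if (!object@imputation %in% c("marginal", "conditional"))
    return("imputation must be 'marginal' or 'conditional'")
  if (object@credibleLevel <= 0 || object@credibleLevel >= 1)
    return("credibleLevel must lie in (0, 1)")
  if (object@mhStep <= 0) return("mhStep must be positive")
  need <- c("beta", "alpha", "delta", "omega", "u", "sigma")
  if (!all(need %in% names(object@update)))
    return("update must name beta, alpha, delta, omega, u and sigma flags")
  TRUE
})

#' One point of the sampler's state space
#'
#' All unknowns of the augmented model: the structural parameters, the latent
#' confounder values U (one per individual), and the current imputations of
#' the missing outcomes (group B) and exposures (group C).
#'
#' @slot beta causal effects.
#' @slot alpha instrument strengths, ordered as in the [ModelGraph-class].
#' @slot delta confounder effects (exposures, then outcome).
#' @slot omega intercepts (exposures, then outcome).
#' @slot sigma residual standard deviations (exposures, then outcome); all
#'   positive.
#' @slot U latent confounder values, one per data row.
#' @slot Yimp imputed outcomes for group-B rows.
#' @slot Ximp imputed exposure matrix for group-C rows.
#'
#' @seealso [initializeState()]
#' @export
setClass("ParameterState",
  representation(beta = "numeric", alpha = "numeric", delta = "numeric",
    omega = "numeric", sigma = "numeric", U = "numeric",
    Yimp = "numeric", Ximp = "matrix"))

setValidity("ParameterState", function(object) {
  if (any(object@sigma <= 0)) return("all sigma must be positive")
  K <- length(object@beta)
  if (length(object@delta) != K + 1L || length(object@omega) != K + 1L ||
      length(object@sigma) != K + 1L)
    return("delta, omega and sigma must have length length(beta) + 1")
  if (nrow(object@Ximp) > 0L && ncol(object@Ximp) != K)
    return("Ximp must have one column per exposure")
  TRUE
})

#' Posterior summary of a fitted Bayesian MR model
#'
#' Post-warmup draws (chains concatenated) together with per-parameter
#' summaries: posterior mean and sd, equal-tailed credible interval, split
#' R-hat and effective sample size.
#'
#' @slot draws numeric matrix, one column per parameter, one row per retained
#'   draw.
#' @slot chain integer chain id of each retained draw.
#' @slot summary data.frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`, `rhat`, `ess`.
#' @slot level credible level of `lower`/`upper`.
#' @slot seed seed used for the run.
#'
#' @seealso [runChain()]
#' @export
setClass("MRPosterior",
  representation(draws = "matrix", chain = "integer", summary = "data.frame",
    level = "numeric", seed = "integer"))

#' Classic Mendelian randomization estimate
#'
#' Point estimates, standard errors and normal-theory 95% confidence
#' intervals for the causal effect of each exposure, from either one-sample
#' two-stage least squares (`"2SLS"`) or two-sample multivariable
#' inverse-variance weighted estimation (`"IVW"`).
#'
#' @slot betaHat estimated causal effects.
#' @slot se standard errors.
#' @slot ci matrix with columns `lower`, `upper` (estimate +/- 1.96 se).
#' @slot method `"2SLS"` or `"IVW"`.
#'
#' @seealso [fit2sls()], [fitIVW()], [classicForDesign()]
#' @export
setClass("ClassicEstimate",
  representation(betaHat = "numeric", se = "numeric", ci = "matrix",
    method = "character"))

setValidity("ClassicEstimate", function(object) {
  if (!object@method %in% c("2SLS", "IVW"))
    return("method must be '2SLS' or 'IVW'")
  if (any(object@se <= 0)) return("standard errors must be positive")
  if (nrow(object@ci) != length(object@betaHat) || ncol(object@ci) != 2L)
    return("ci must be a length(betaHat) x 2 matrix")
  TRUE
})

#' Two-sample summary statistics
#'
#' Per-instrument association estimates feeding the IVW estimator:
#' instrument-exposure slopes `gammaHat` (from the exposure-side rows) and
#' instrument-outcome slopes `GammaHat` (from the outcome-side rows), each
#' from a simple regression with intercept, with standard errors.
#'
#' @slot gammaHat,gammaSe instruments x exposures matrices.
#' @slot GammaHat,GammaSe per-instrument outcome slopes and standard errors.
#' @slot nB,nC numbers of exposure-side and outcome-side rows used.
#'
#' @seealso [computeSummaryStats()], [fitIVW()]
#' @export
setClass("SummaryStats",
  representation(gammaHat = "matrix", gammaSe = "matrix",
    GammaHat = "numeric", GammaSe = "numeric",
    nB = "integer", nC = "integer"))

setValidity("SummaryStats", function(object) {
  if (any(object@gammaSe <= 0) || any(object@GammaSe <= 0))
    return("standard errors must be positive")
  if (length(object@GammaHat) != nrow(object@gammaHat))
    return("GammaHat must have one entry per instrument")
  TRUE
})
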
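## Synthetic-data generator for overlapping-sample MR designs.
##
## The generative law is the structural model itself: a latent scalar
## confounder U ~ N(0, uVar) drives every exposure and the outcome; each
## exposure is a linear function of its instruments and U; the outcome is a
## linear function of the exposures and U. Overlapping designs are obtained
## by carving a fully observed population into a complete subset A, an
## exposure-only subset B and an outcome-only subset C.

#' Split a study of given size into overlapping and non-overlapping parts
#'
#' The instrument-exposure study D1 = A + B and the instrument-outcome study
#' D2 = A + C both have `nStudy` individuals; the overlap rate is the
#' fraction contributed by the shared complete subset A. B and C have equal
#' size by design.
#'
#' @param overlapRate fraction in `[0, 1]`.
#' @param nStudy per-study sample size.
#'
#' @return Named list with integer components `nA`, `nB`, `nC`
#'   (`nA + nB == nStudy`, `nB == nC`). `overlapRate * nStudy` is rounded
#'   half-to-even when not an integer.
#' @examples
#' computeSplitSizes(0.8, 400)  # nA = 320, nB = nC = 80
#' @export
computeSplitSizes <- function(overlapRate, nStudy) {
  if (length(overlapRate) != 1L || is.na(overlapRate) ||
      overlapRate < 0 || overlapRate > 1)
    stop("'overlapRate' must be a single value in [0, 1]")
  if (length(nStudy) != 1L || is.na(nStudy) || nStudy <= 0)
    stop("'nStudy' must be a positive count")
  nStudy <- as.integer(nStudy)
  nA <- as.integer(round(overlapRate * nStudy))
  list(nA = nA, nB = nStudy - nA, nC = nStudy - nA)
}

## n x K matrix of instrument-driven exposure means: omega_k + sum_j alpha_jk z_j.
## alpha is ordered column-major over the TRUE entries of the loading matrix.
exposureMeans <- function(Z, graph, alpha, omega) {
  L <- graph@loadings
  K <- ncol(L)
  A <- matrix(0, nrow(L), K)
  A[L] <- alpha
  Z %*% A + rep(omega[seq_len(K)], each = nrow(Z))
}

#' Generate a fully observed population from the structural model
#'
#' Per individual: latent confounder \eqn{U \sim N(0, \mathrm{uVarTrue})};
#' exposures \eqn{X_k = \omega_k + \sum_j \alpha_{jk} Z_j + \delta_k U +
#' \epsilon_k}; outcome \eqn{Y = \omega_Y + \beta^\top X + \delta_{K+1} U +
#' \epsilon_Y}; independent normal noise with the configured standard
#' deviations. Instruments are independent across columns and individuals,
#' either `Binomial(2, maf)` dosages or standard normal.
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional integer seed for reproducibility.
#'
#' @return An [MRData-class] of `config@nPopulation` complete rows (all
#'   group `"A"`).
#' @seealso [splitIntoABC()]
#' @export
generatePopulation <- function(config, seed = NULL) {
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config@nPopulation
  J <- nrow(config@graph@loadings)
  K <- ncol(config@graph@loadings)
  Z <- if (config@zDist == "binomial") {
    matrix(stats::rbinom(n * J, 2L, config@maf), n, J)
  } else {
    matrix(stats::rnorm(n * J), n, J)
  }
  colnames(Z) <- paste0("Z", seq_len(J))
  U <- stats::rnorm(n, 0, sqrt(config@uVarTrue))
  mu <- exposureMeans(Z, config@graph, config@alphaTrue, config@omegaTrue)
  eps <- matrix(stats::rnorm(n * K), n, K) %*% diag(config@sigmaTrue[seq_len(K)], K)
  X <- mu + outer(U, config@deltaTrue[seq_len(K)]) + eps
  colnames(X) <- paste0("X", seq_len(K))
  Y <- config@omegaTrue[K + 1L] + drop(X %*% config@betaTrue) +
    config@deltaTrue[K + 1L] * U +
    stats::rnorm(n, 0, config@sigmaTrue[K + 1L])
  mrData(Z, X, Y, group = rep("A", n))
}

#' Carve a population into overlapping datasets A, B and C
#'
#' Samples `nA`, then `nB`, then `nC` individuals without replacement from
#' the population; the three subsets are disjoint. Subset A keeps all
#' variables; B keeps instruments and exposures (outcome masked); C keeps
#' instruments and outcome (exposures masked). Unsampled rows are discarded.
#'
#' @param H an [MRData-class] population of complete rows.
#' @param sizes list with `nA`, `nB`, `nC` (see [computeSplitSizes()]).
#' @param seed optional integer seed.
#'
#' @return An [MRData-class] with `nA + nB + nC` rows and group labels.
#' @export
splitIntoABC <- function(H, sizes, seed = NULL) {
  validObject(H)
  stopifnot(all(c("nA", "nB", "nC") %in% names(sizes)))
  if (any(H@group != "A"))
    stop("'H' must be a fully observed population (all rows complete)")
  nTot <- sizes$nA + sizes$nB + sizes$nC
  if (nTot > nIndividuals(H))
    stop("requested sizes exceed the population size")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nIndividuals(H), nTot, replace = FALSE)
  iA <- idx[seq_len(sizes$nA)]
  iB <- idx[sizes$nA + seq_len(sizes$nB)]
  iC <- idx[sizes$nA + sizes$nB + seq_len(sizes$nC)]
  keep <- c(iA, iB, iC)
  Z <- H@Z[keep, , drop = FALSE]
  X <- H@X[keep, , drop = FALSE]
  Y <- H@Y[keep]
  group <- rep(c("A", "B", "C"), c(sizes$nA, sizes$nB, sizes$nC))
  Y[group == "B"] <- NA_real_
  X[group == "C", ] <- NA_real_
  mrData(Z, X, Y, group = group)
}

#' Generate one overlapping-sample dataset in a single call
#'
#' Convenience wrapper: [generatePopulation()] then [splitIntoABC()] with
#' sizes from [computeSplitSizes()] at the configuration's overlap rate.
#'
#' @inheritParams generatePopulation
#' @return An [MRData-class].
#' @export
simulateDesign <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- generatePopulation(config, seed = NULL)
  splitIntoABC(H, computeSplitSizes(config@overlapRate, config@nStudy))
}
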
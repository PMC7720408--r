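## Classic frequentist comparators: multivariable two-stage least squares on
## complete (one-sample) data, and multivariable inverse-variance weighted
## estimation from per-instrument summary statistics for two-sample data.

classicEstimate <- function(betaHat, se, method) {
  ci <- cbind(lower = betaHat - 1.96 * se, upper = betaHat + 1.96 * se)
  new("ClassicEstimate", betaHat = unname(betaHat), se = unname(se),
    ci = unname(ci) , method = method)
}

#' Multivariable two-stage least squares
#'
#' Stage 1 regresses each exposure on an intercept and all instruments;
#' stage 2 regresses the outcome on an intercept and the fitted exposures.
#' Standard errors are the conventional homoskedastic 2SLS form, with the
#' residual variance recomputed from the observed (not fitted) exposures.
#'
#' @param data a complete [MRData-class] (no missing cells; at least as many
#'   instruments as exposures).
#'
#' @return A [ClassicEstimate-class] with method `"2SLS"`.
#' @export
fit2sls <- function(data) {
  validObject(data)
  if (anyNA(data@X) || anyNA(data@Y))
    stop("fit2sls needs complete data (100% overlap); see classicForDesign()")
  Z <- cbind(1, data@Z)
  X <- cbind(1, data@X)
  y <- data@Y
  n <- length(y); p <- ncol(X)
  if (ncol(Z) < p) stop("need at least as many instruments as exposures")
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) stop("singular design: first-stage instrument matrix")
  Xhat <- qr.fitted(qrZ, X)
  XtX <- crossprod(Xhat)
  R <- tryCatch(chol(XtX), error = function(e)
    stop("singular design: fitted exposures are collinear"))
  coef <- backsolve(R, backsolve(R, crossprod(Xhat, y), transpose = TRUE))
  resid <- y - drop(X %*% coef)              # observed X in the residual
  s2 <- sum(resid^2) / (n - p)
  covB <- s2 * chol2inv(R)
  classicEstimate(drop(coef)[-1L], sqrt(diag(covB))[-1L], "2SLS")
}

#' Per-instrument summary statistics for two-sample analysis
#'
#' Instrument-exposure slopes from the exposure-side rows (groups with
#' observed X; by default group B) and instrument-outcome slopes from the
#' outcome-side rows (group C), each from a simple linear regression with
#' intercept, with conventional standard errors.
#'
#' @param data an [MRData-class].
#' @param exposureGroups,outcomeGroups group labels contributing to each
#'   side.
#'
#' @return A [SummaryStats-class].
#' @export
computeSummaryStats <- function(data, exposureGroups = "B",
                                outcomeGroups = "C") {
  b <- data@group %in% exposureGroups
  cc <- data@group %in% outcomeGroups
  if (!any(b) || !any(cc))
    stop("need rows on both the exposure side and the outcome side")
  Zb <- data@Z[b, , drop = FALSE]; Xb <- data@X[b, , drop = FALSE]
  Zc <- data@Z[cc, , drop = FALSE]; Yc <- data@Y[cc]
  if (anyNA(Xb)) stop("exposure-side rows must observe all exposures")
  if (anyNA(Yc)) stop("outcome-side rows must observe the outcome")
  J <- ncol(data@Z); K <- ncol(data@X)
  g <- gse <- matrix(NA_real_, J, K)
  G <- Gse <- numeric(J)
  for (j in seq_len(J)) {
    for (k in seq_len(K)) {
      f <- simpleSlope(Zb[, j], Xb[, k])
      g[j, k] <- f$slope; gse[j, k] <- f$se
    }
    f <- simpleSlope(Zc[, j], Yc)
    G[j] <- f$slope; Gse[j] <- f$se
  }
  new("SummaryStats", gammaHat = g, gammaSe = gse, GammaHat = G,
    GammaSe = Gse, nB = sum(b), nC = sum(cc))
}

## slope and classical se of lm(y ~ z)
simpleSlope <- function(z, y) {
  n <- length(z)
  vz <- sum((z - mean(z))^2)
  if (vz <= 0) stop("zero-variance instrument")
  slope <- sum((z - mean(z)) * (y - mean(y))) / vz
  resid <- y - mean(y) - slope * (z - mean(z))
  list(slope = slope, se = sqrt(sum(resid^2) / (n - 2) / vz))
}

#' Multivariable inverse-variance weighted estimation
#'
#' Weighted least squares of the instrument-outcome associations on the
#' instrument-exposure association matrix, with fixed-effect weights equal to
#' the inverse squared standard errors of the outcome associations:
#' \eqn{\hat\beta = \mathrm{argmin} \sum_j w_j (\hat\Gamma_j -
#' \sum_k \hat\gamma_{jk}\beta_k)^2}. In the exactly identified case (as many
#' instruments as exposures) the point estimate reduces to
#' \eqn{\hat\gamma^{-1}\hat\Gamma} whatever the weights.
#'
#' @param stats a [SummaryStats-class].
#'
#' @return A [ClassicEstimate-class] with method `"IVW"`.
#' @export
fitIVW <- function(stats) {
  g <- stats@gammaHat
  w <- 1 / stats@GammaSe^2
  A <- crossprod(g, w * g)
  R <- tryCatch(chol(A), error = function(e)
    stop("singular instrument-exposure association matrix: ",
      "instruments may be weak or collinear"))
  betaHat <- backsolve(R, backsolve(R, crossprod(g, w * stats@GammaHat),
    transpose = TRUE))
  covB <- chol2inv(R)
  classicEstimate(drop(betaHat), sqrt(diag(covB)), "IVW")
}

#' Design-appropriate classic estimator
#'
#' Complete data (100% overlap) are analysed by one-sample 2SLS on all rows;
#' any design with missing cells is analysed by two-sample IVW using the
#' non-overlapping rows only (group B for the exposure side, group C for the
#' outcome side), discarding the shared complete rows.
#'
#' @param data an [MRData-class].
#' @return A [ClassicEstimate-class].
#' @export
classicForDesign <- function(data) {
  gs <- groupSizes(data)
  if (gs["nB"] == 0L && gs["nC"] == 0L) return(fit2sls(data))
  if (gs["nB"] == 0L || gs["nC"] == 0L)
    stop("partially overlapping design needs rows in both groups B and C")
  fitIVW(computeSummaryStats(data))
}
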
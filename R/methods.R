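#' @describeIn MRData-class instrument matrix.
#' @param x,object an `MRData` object.
#' @export
instruments <- function(x) x@Z

#' @describeIn MRData-class exposure matrix (with `NA` on group-C rows).
#' @export
exposures <- function(x) x@X

#' @describeIn MRData-class outcome vector (with `NA` on group-B rows).
#' @export
outcome <- function(x) x@Y

#' @describeIn MRData-class group labels (`"A"`, `"B"`, `"C"`).
#' @export
groupLabels <- function(x) x@group

#' @describeIn MRData-class number of individuals.
#' @export
nIndividuals <- function(x) nrow(x@Z)

#' @describeIn MRData-class named counts of the three groups.
#' @export
groupSizes <- function(x) {
  g <- factor(x@group, levels = c("A", "B", "C"))
  stats::setNames(as.integer(table(g)), c("nA", "nB", "nC"))
}

setMethod("show", "MRData", function(object) {
  gs <- groupSizes(object)
  cat("MRData with", nIndividuals(object), "individuals,",
    ncol(object@Z), "instruments,", ncol(object@X), "exposures\n")
  cat(sprintf("  groups: A (complete) %d | B (Y missing) %d | C (X missing) %d\n",
    gs["nA"], gs["nB"], gs["nC"]))
})

setMethod("show", "ModelGraph", function(object) {
  cat("ModelGraph:", nrow(object@loadings), "instruments,",
    ncol(object@loadings), "exposures,", nAlpha(object), "loading edges\n")
  print(object@loadings)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  overlap rate:", object@overlapRate,
    " population:", object@nPopulation, " study size:", object@nStudy, "\n")
  cat("  alpha:", paste(object@alphaTrue, collapse = ", "), "\n")
  cat("  beta: ", paste(object@betaTrue, collapse = ", "), "\n")
  cat("  delta:", paste(object@deltaTrue, collapse = ", "), "\n")
  cat("  sigma:", paste(object@sigmaTrue, collapse = ", "),
    " instruments:", object@zDist, "\n")
})

setMethod("show", "MRPosterior", function(object) {
  cat("MRPosterior:", nrow(object@draws), "retained draws,",
    length(unique(object@chain)), "chain(s)\n")
  s <- object@summary
  main <- s[grepl("^beta", s$parameter), , drop = FALSE]
  print(cbind(main[, "parameter", drop = FALSE],
    round(main[, c("mean", "sd", "lower", "upper", "rhat", "ess")], 4)),
    row.names = FALSE)
})

setMethod("show", "ClassicEstimate", function(object) {
  cat("ClassicEstimate (", object@method, ")\n", sep = "")
  out <- data.frame(exposure = seq_along(object@betaHat),
    estimate = round(object@betaHat, 4), se = round(object@se, 4),
    lower = round(object@ci[, 1], 4), upper = round(object@ci[, 2], 4))
  print(out, row.names = FALSE)
})

#' @describeIn MRPosterior-class retained posterior draws (matrix).
#' @param object an `MRPosterior`.
#' @export
posteriorDraws <- function(object) object@draws

#' @describeIn MRPosterior-class per-parameter summary data.frame.
#' @export
posteriorSummary <- function(object) object@summary

#' @describeIn ClassicEstimate-class point estimates of the causal effects.
#' @param object a `ClassicEstimate`.
#' @export
classicBeta <- function(object) object@betaHat
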
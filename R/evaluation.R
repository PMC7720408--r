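## Simulation-study harness: run replicate datasets over a grid of
## conditions and summarize each (condition x exposure x method) cell by the
## mean and sd of the point estimates and by coverage and power of the 95%
## intervals.

#' Specify a simulation grid
#'
#' The default grid is the full factorial of 6 overlap rates, 2 instrument
#' strengths, 3 confounding levels and 2 causal-effect levels — 72
#' conditions.
#'
#' @param overlapRates,alphaLevels,deltaLevels,betaLevels factor levels.
#' @param nReplicates replicate datasets per condition.
#' @param baseSeed base seed from which per-replicate seeds are derived.
#'
#' @return A data.frame with one row per condition (attributes carry
#'   `nReplicates` and `baseSeed`).
#' @export
gridSpec <- function(overlapRates = c(1, 0.8, 0.6, 0.4, 0.2, 0),
                     alphaLevels = c(0.5, 0.1),
                     deltaLevels = c(1, 0.5, 0.1),
                     betaLevels = c(0.3, 0),
                     nReplicates = 200L, baseSeed = 1L) {
  grid <- expand.grid(beta = betaLevels, delta = deltaLevels,
    alpha = alphaLevels, overlap = overlapRates,
    KEEP.OUT.ATTRS = FALSE)[, c("overlap", "alpha", "delta", "beta")]
  grid <- grid[order(-grid$overlap, -grid$alpha, -grid$delta, -grid$beta), ]
  rownames(grid) <- NULL
  attr(grid, "nReplicates") <- as.integer(nReplicates)
  attr(grid, "baseSeed") <- as.integer(baseSeed)
  grid
}

#' Deterministic per-replicate seed
#'
#' Mixes the base seed, the condition index and the replicate index so any
#' single cell of a grid can be re-run in isolation.
#'
#' @param baseSeed,configIndex,replicateIndex integers.
#' @return An integer seed in `[1, 2^31)`.
#' @export
replicateSeed <- function(baseSeed, configIndex, replicateIndex) {
  m <- 2147483629
  s <- (as.numeric(baseSeed) %% m) * 1000003 %% m
  s <- (s + as.numeric(configIndex) * 10007 + as.numeric(replicateIndex) * 101) %% m
  as.integer(s + 1)
}

#' Run one simulation replicate
#'
#' Generates a population, carves it into the overlapping design, fits the
#' Bayesian model and the design-appropriate classic estimator, and returns
#' one row per exposure and method with the point estimate and 95% interval
#' (posterior mean and credible interval for the Bayesian fit; +/- 1.96 se
#' for the classic fit).
#'
#' @param config a [SimulationConfig-class].
#' @param sampler a [SamplerConfig-class].
#' @param seed integer seed for this replicate.
#' @param priors a [PriorSpec-class].
#' @param methods character subset of `c("Bayesian", "Classic")`.
#'
#' @return A data.frame with columns `method`, `exposure`, `estimate`,
#'   `lower`, `upper`.
#' @export
runReplicate <- function(config, sampler = samplerConfig(), seed = 1L,
                         priors = priorSpec(),
                         methods = c("Bayesian", "Classic")) {
  d <- simulateDesign(config, seed = seed)
  K <- ncol(config@graph@loadings)
  out <- list()
  if ("Bayesian" %in% methods) {
    ## decouple the chain's RNG stream from the data-generation stream
    chainSeed <- (as.numeric(seed) + 715827881) %% 2147483629
    fit <- runChain(d, priors = priors, config = sampler, seed = chainSeed,
      graph = config@graph)
    s <- fit@summary[seq_len(K), ]
    out$bayes <- data.frame(method = "Bayesian", exposure = seq_len(K),
      estimate = s$mean, lower = s$lower, upper = s$upper)
  }
  if ("Classic" %in% methods) {
    cl <- classicForDesign(d)
    out$classic <- data.frame(method = "Classic", exposure = seq_len(K),
      estimate = cl@betaHat, lower = cl@ci[, 1L], upper = cl@ci[, 2L])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate replicate estimates into performance metrics
#'
#' For each method and exposure: the mean and standard deviation (n-1
#' denominator) of the point estimates over replicates, the coverage of the
#' intervals (fraction containing the true effect) and, when the true effect
#' is non-zero, the power (fraction of intervals excluding zero).
#'
#' @param results row-bound output of [runReplicate()] over replicates.
#' @param truth true causal effect per exposure (recycled).
#'
#' @return A data.frame with columns `method`, `exposure`, `mean`, `sd`,
#'   `coverage`, `power` (`NA` under the null) and `nReplicates`.
#' @export
aggregateReplicates <- function(results, truth) {
  if (nrow(results) == 0L) stop("no successful replicates to aggregate")
  K <- max(results$exposure)
  truth <- rep_len(truth, K)
  cells <- split(results,
    list(method = results$method, exposure = results$exposure))
  cells <- cells[vapply(cells, nrow, 0L) > 0L]
  rows <- lapply(cells, function(cell) {
    k <- cell$exposure[1L]
    data.frame(method = cell$method[1L], exposure = k,
      mean = mean(cell$estimate),
      sd = stats::sd(cell$estimate),
      coverage = mean(cell$lower <= truth[k] & truth[k] <= cell$upper),
      power = if (truth[k] != 0)
        mean(cell$lower > 0 | cell$upper < 0) else NA_real_,
      nReplicates = nrow(cell))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$exposure, out$method), ]
  rownames(out) <- NULL
  out
}

#' Run a simulation grid
#'
#' Runs `nReplicates` replicate datasets for every condition of the grid and
#' aggregates them with [aggregateReplicates()]. Replicates whose fit fails
#' are recorded (condition, replicate index, error message) and excluded
#' from the metrics with a logged count.
#'
#' @param grid a [gridSpec()] data.frame.
#' @param sampler a [SamplerConfig-class] used for every Bayesian fit.
#' @param priors a [PriorSpec-class].
#' @param nReplicates overrides the grid's replicate count when given.
#' @param baseSeed overrides the grid's base seed when given.
#' @param methods character subset of `c("Bayesian", "Classic")`.
#' @param outDir optional directory; when given, writes `table1.csv`
#'   (non-null conditions, with power), `table2.csv` (null conditions,
#'   without power) and `replicates.csv`.
#' @param verbose print a line per condition.
#'
#' @return A data.frame of metrics, one row per condition x exposure x
#'   method, with the per-replicate estimates in `attr(, "replicates")` and
#'   any failures in `attr(, "failures")`.
#' @export
runGrid <- function(grid = gridSpec(), sampler = samplerConfig(),
                    priors = priorSpec(), nReplicates = NULL,
                    baseSeed = NULL, methods = c("Bayesian", "Classic"),
                    outDir = NULL, verbose = FALSE) {
  nRep <- if (is.null(nReplicates)) attr(grid, "nReplicates") else
    as.integer(nReplicates)
  seed0 <- if (is.null(baseSeed)) attr(grid, "baseSeed") else
    as.integer(baseSeed)
  if (is.null(nRep) || is.null(seed0))
    stop("grid must carry nReplicates and baseSeed (see gridSpec())")
  metrics <- list(); reps <- list(); fails <- list()
  for (i in seq_len(nrow(grid))) {
    cond <- grid[i, ]
    cfg <- simConfig(overlapRate = cond$overlap, alphaTrue = cond$alpha,
      betaTrue = cond$beta, deltaTrue = cond$delta)
    res <- list()
    for (r in seq_len(nRep)) {
      one <- tryCatch(
        runReplicate(cfg, sampler = sampler,
          seed = replicateSeed(seed0, i, r), priors = priors,
          methods = methods),
        error = function(e) e)
      if (inherits(one, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(configIndex = i,
          replicate = r, message = conditionMessage(one))
      } else {
        one$replicate <- r
        res[[r]] <- one
      }
    }
    if (length(res) == 0L)
      stop(sprintf("all replicates failed for condition %d", i))
    res <- do.call(rbind, res)
    m <- aggregateReplicates(res, truth = cfg@betaTrue)
    m <- cbind(cond[rep(1L, nrow(m)), , drop = FALSE], m, row.names = NULL)
    metrics[[i]] <- m
    reps[[i]] <- cbind(cond[rep(1L, nrow(res)), , drop = FALSE], res,
      row.names = NULL)
    if (verbose)
      message(sprintf("[%s] condition %d/%d done (%d replicates)",
        format(Sys.time(), "%H:%M:%S"), i, nrow(grid), nRep))
  }
  metrics <- do.call(rbind, metrics)
  replicates <- do.call(rbind, reps)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(configIndex = integer(0), replicate = integer(0),
      message = character(0))
  if (nrow(failures) > 0L)
    message(sprintf("%d replicate fit(s) failed and were excluded",
      nrow(failures)))
  attr(metrics, "replicates") <- replicates
  attr(metrics, "failures") <- failures
  if (!is.null(outDir)) writeGridTables(metrics, outDir)
  metrics
}

#' Write grid metrics in the two-table layout
#'
#' `table1.csv` holds the non-null conditions (with the power column),
#' `table2.csv` the null conditions (without it), `replicates.csv` the
#' per-replicate estimates.
#'
#' @param metrics output of [runGrid()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeGridTables <- function(metrics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alt <- metrics[metrics$beta != 0, , drop = FALSE]
  null <- metrics[metrics$beta == 0, , drop = FALSE]
  null$power <- NULL
  utils::write.csv(alt, file.path(dir, "table1.csv"), row.names = FALSE)
  utils::write.csv(null, file.path(dir, "table2.csv"), row.names = FALSE)
  reps <- attr(metrics, "replicates")
  if (!is.null(reps))
    utils::write.csv(reps, file.path(dir, "replicates.csv"),
      row.names = FALSE)
  invisible(dir)
}
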
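# Landscape diagnostics: distance-to-canonical scatters, inter-distance
# histograms, canonical-code survival, ensemble summaries and the p.d.m.

#' Distances of a population to the canonical code
#'
#' Pairs every individual of a population snapshot with its distance to the
#' canonical genotype and its raw cost under a scheme; the analysis behind
#' the distance-versus-cost scatter plots.
#'
#' @param pop Character matrix of genotypes (one per row).
#' @param scheme Weight scheme for the cost axis.
#' @param scale Property scale.
#' @return data.frame with columns \code{distance} (in [0, 1]) and
#'   \code{cost}, one row per individual.
#' @export
distancesToCanonical <- function(pop, scheme = c("ms", "tms"),
                                 scale = polarRequirement()) {
  scheme <- match.arg(scheme)
  popInt <- .toInternal(pop)
  model <- if (ncol(popInt) == .N_AA) "restrictive" else "unrestrictive"
  canon <- .toInternal(canonicalGenotype(model))
  both <- rbind(canon, popInt)
  d <- .distMatInternal(both, scale)[1L, -1L]
  data.frame(distance = d,
             cost = .populationCosts(popInt, model, scheme, scale))
}

#' Inter-distance histogram of a population
#'
#' Histogram of all unordered pairwise code distances of a population, with
#' 100 bins of width 0.01 over [0, 1]: left-closed, right-open, except the
#' last bin which is closed at 1. Counts sum to \code{n(n-1)/2}. Near-zero
#' inter-distances flag clusters (niches) of the population.
#'
#' @param pop Character matrix of genotypes.
#' @param scale Property scale.
#' @return data.frame with columns \code{binLeft} (0.00, 0.01, ..., 0.99)
#'   and \code{count}.
#' @export
interdistanceHistogram <- function(pop, scale = polarRequirement()) {
  d <- .distMatInternal(.toInternal(pop), scale)
  dv <- d[lower.tri(d)]
  idx <- pmin(floor(dv / 0.01) + 1L, 100L)
  data.frame(binLeft = seq(0, 0.99, by = 0.01),
             count = tabulate(idx, 100L))
}

#' Generation at which the canonical code disappears
#'
#' For a run that seeded the canonical genotype into the initial
#' population, returns the first generation at which no individual equals
#' the canonical genotype (exact genotype equality), or the character
#' string \code{"survived"} if it is still present at the final generation.
#'
#' @param record A \code{\linkS4class{RunRecord}} from a run with
#'   \code{seedCanonical = TRUE}.
#' @return Integer generation index (>= 1) or \code{"survived"}.
#' @export
canonicalSurvival <- function(record) {
  if (!record@config@seedCanonical)
    stop("the run was executed without canonical seeding")
  pres <- record@stats$canonicalPresent
  if (pres[length(pres)]) return("survived")
  record@stats$generation[which(!pres)[1L]]
}

#' p.d.m. of the canonical code from a run ensemble
#'
#' Evaluates the percentage distance minimization with the canonical cost
#' (under the ensemble's scheme) as the code value, the random-code mean
#' from \code{randomStats}, and the best raw cost over all records as the
#' low value.
#'
#' @param records List of \code{RunRecord}s sharing a configuration.
#' @param randomStats Result of \code{\link{sampleRandomStatistics}} for
#'   the matching model and scheme.
#' @return The p.d.m. percentage.
#' @seealso \code{\link{pdm}}
#' @export
pdmFromEnsemble <- function(records, randomStats) {
  if (!length(records)) stop("need at least one run record")
  scheme <- records[[1L]]@config@scheme
  canon <- msError(canonicalCode(), scheme)
  low <- min(vapply(records, bestCost, numeric(1)))
  pdm(canon, randomStats$mean, low)
}

#' Summarize a run ensemble
#'
#' Mean and standard deviation, over runs, of the final-generation best and
#' average raw costs, rounded to 2 decimals for direct comparison with
#' summary tables.
#'
#' @param records List of \code{RunRecord}s; all must share the same
#'   configuration apart from the seed.
#' @return data.frame with columns \code{condition}, \code{metric}
#'   (\code{"best"} / \code{"average"}), \code{mean}, \code{sd}.
#' @export
summarizeEnsemble <- function(records) {
  if (!length(records)) stop("need at least one run record")
  cfgs <- lapply(records, function(r) {
    c0 <- r@config; c0@rngSeed <- 0L; c0
  })
  for (i in seq_along(cfgs))
    if (!identical(cfgs[[i]], cfgs[[1L]]))
      stop("records mix different configurations")
  fin <- t(vapply(records, function(r) {
    s <- r@stats[nrow(r@stats), ]
    c(best = s$bestCost, avg = s$meanCost)
  }, numeric(2)))
  cfg <- records[[1L]]@config
  cond <- sprintf("%s/%s, %s", cfg@model, cfg@scheme,
                  if (is.na(cfg@sigmaShare)) "no sharing"
                  else sprintf("sigma_share=%g", cfg@sigmaShare))
  data.frame(
    condition = cond, metric = c("best", "average"),
    mean = round(c(mean(fin[, "best"]), mean(fin[, "avg"])), 2),
    sd = round(c(if (nrow(fin) > 1) sd(fin[, "best"]) else 0,
                 if (nrow(fin) > 1) sd(fin[, "avg"]) else 0), 2))
}

#' Minimal base-graphics views of the two landscape diagnostics
#'
#' \code{plotDistanceScatter} draws the cost-versus-distance scatter of
#' \code{\link{distancesToCanonical}}; \code{plotInterdistanceHistogram}
#' draws the binned counts of \code{\link{interdistanceHistogram}}.
#'
#' @param scatter,histogram The respective data.frames.
#' @param ... Passed to the underlying base plotting call.
#' @return Invisibly, the input.
#' @name landscape-plots
NULL

#' @rdname landscape-plots
#' @importFrom graphics plot
#' @export
plotDistanceScatter <- function(scatter, ...) {
  plot(scatter$distance, scatter$cost, xlim = c(0, 1), pch = 20,
       xlab = "distance to canonical code", ylab = "error cost", ...)
  invisible(scatter)
}

#' @rdname landscape-plots
#' @importFrom graphics barplot
#' @export
plotInterdistanceHistogram <- function(histogram, ...) {
  barplot(histogram$count, names.arg = histogram$binLeft, space = 0,
          xlab = "inter-distance", ylab = "pair count", ...)
  invisible(histogram)
}
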
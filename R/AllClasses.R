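# S4 classes: GAConfig (all evolutionary and sharing parameters plus
# seeds) and RunRecord (per-generation statistics and the final population
# of one GA run).

#' GAConfig: configuration of a code-evolution run
#'
#' Holds every parameter of the genetic algorithm. Defaults reproduce the
#' package's headline experimental setup: population 1000, 100 generations,
#' swap probability 0.5, per-position mutation probability 0.01
#' (unrestrictive model only), tournament window of 3% of the population,
#' elitism on, sharing off.
#'
#' @slot model Code model, \code{"restrictive"} or \code{"unrestrictive"}.
#' @slot scheme Weight scheme, \code{"ms"} or \code{"tms"}.
#' @slot populationSize Number of individuals (>= 2).
#' @slot generations Number of generation steps.
#' @slot mutationProb Per-position mutation probability (unrestrictive
#'   model; ignored by the restrictive model, which has no mutation
#'   operator).
#' @slot mutationPerPosition If FALSE, \code{mutationProb} is read as a
#'   per-individual probability of mutating one random position instead.
#' @slot swapProb Probability governing swap applications per offspring.
#' @slot swapCount \code{"single"} (default): at most one swap
#'   application per offspring, firing with probability \code{swapProb};
#'   \code{"geometric"}: applications repeat while the \code{swapProb}
#'   coin keeps firing (geometric count, mean one at the default 0.5),
#'   which adds compound two-swap moves and escapes shallow swap-local
#'   optima at the price of a larger variant load in the population.
#' @slot tournamentFraction Tournament window as a fraction of the
#'   population; the window is \code{round(fraction * populationSize)},
#'   at least 1.
#' @slot sigmaShare Sharing radius in (0, 1]; \code{NA} disables sharing.
#' @slot alpha Sharing level (> 0).
#' @slot elitism Keep the best raw-cost individual unchanged each
#'   generation.
#' @slot seedCanonical Replace one random individual of the initial
#'   population by the canonical genotype.
#' @slot rngSeed Master seed.
#' @slot nRuns Number of independent runs for \code{\link{multiRun}}.
#' @seealso \code{\link{runGA}}, \code{\link{multiRun}}
#' @exportClass GAConfig
setClass("GAConfig",
  representation(
    model = "character", scheme = "character",
    populationSize = "integer", generations = "integer",
    mutationProb = "numeric", mutationPerPosition = "logical",
    swapProb = "numeric", swapCount = "character",
    tournamentFraction = "numeric",
    sigmaShare = "numeric", alpha = "numeric",
    elitism = "logical", seedCanonical = "logical",
    rngSeed = "integer", nRuns = "integer"),
  prototype(
    model = "restrictive", scheme = "ms",
    populationSize = 1000L, generations = 100L,
    mutationProb = 0.01, mutationPerPosition = TRUE,
    swapProb = 0.5, swapCount = "single", tournamentFraction = 0.03,
    sigmaShare = NA_real_, alpha = 1,
    elitism = TRUE, seedCanonical = FALSE,
    rngSeed = 1L, nRuns = 10L))

setValidity("GAConfig", function(object) {
  msg <- character(0)
  if (!object@model %in% c("restrictive", "unrestrictive"))
    msg <- c(msg, "model must be 'restrictive' or 'unrestrictive'")
  if (!object@scheme %in% c("ms", "tms"))
    msg <- c(msg, "scheme must be 'ms' or 'tms'")
  if (object@populationSize < 2L)
    msg <- c(msg, "populationSize must be >= 2")
  if (object@generations < 0L) msg <- c(msg, "generations must be >= 0")
  for (p in c("mutationProb", "swapProb", "tournamentFraction")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, paste(p, "must lie in [0, 1]"))
  }
  if (!object@swapCount %in% c("geometric", "single"))
    msg <- c(msg, "swapCount must be 'geometric' or 'single'")
  if (max(1, round(object@tournamentFraction * object@populationSize)) >
      object@populationSize)
    msg <- c(msg, "tournament window exceeds the population")
  if (!is.na(object@sigmaShare) && object@sigmaShare <= 0)
    msg <- c(msg, "sigmaShare must be > 0 (or NA to disable sharing)")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@nRuns < 1L) msg <- c(msg, "nRuns must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a GAConfig
#'
#' @param model,scheme,populationSize,generations,mutationProb,
#'   mutationPerPosition,swapProb,swapCount,tournamentFraction,sigmaShare,alpha,
#'   elitism,seedCanonical,rngSeed,nRuns See the class documentation
#'   (\code{\linkS4class{GAConfig}}).
#' @return A validated \code{GAConfig} object.
#' @examples
#' GAConfig(model = "restrictive", sigmaShare = 0.1)
#' @export
GAConfig <- function(model = "restrictive", scheme = "ms",
                     populationSize = 1000L, generations = 100L,
                     mutationProb = 0.01, mutationPerPosition = TRUE,
                     swapProb = 0.5, swapCount = "single",
                     tournamentFraction = 0.03,
                     sigmaShare = NA_real_, alpha = 1,
                     elitism = TRUE, seedCanonical = FALSE,
                     rngSeed = 1L, nRuns = 10L) {
  new("GAConfig", model = model, scheme = scheme,
      populationSize = as.integer(populationSize),
      generations = as.integer(generations),
      mutationProb = mutationProb,
      mutationPerPosition = mutationPerPosition,
      swapProb = swapProb, swapCount = swapCount,
      tournamentFraction = tournamentFraction,
      sigmaShare = as.numeric(sigmaShare), alpha = alpha,
      elitism = elitism, seedCanonical = seedCanonical,
      rngSeed = as.integer(rngSeed), nRuns = as.integer(nRuns))
}

setMethod("show", "GAConfig", function(object) {
  shr <- if (is.na(object@sigmaShare)) "off"
         else sprintf("sigma=%g, alpha=%g", object@sigmaShare, object@alpha)
  cat("GAConfig:", object@model, "model,", object@scheme, "cost\n",
      sprintf(" pop=%d gens=%d swapProb=%g mutProb=%g tournament=%g%%\n",
              object@populationSize, object@generations, object@swapProb,
              object@mutationProb, 100 * object@tournamentFraction),
      sprintf(" sharing=%s elitism=%s seedCanonical=%s seed=%d runs=%d\n",
              shr, object@elitism, object@seedCanonical, object@rngSeed,
              object@nRuns))
})

#' RunRecord: the result of one GA run
#'
#' @slot config The \code{\linkS4class{GAConfig}} used.
#' @slot seed The run-level seed actually applied.
#' @slot stats data.frame with one row per generation (including the
#'   initial generation 0): \code{generation}, \code{bestCost},
#'   \code{meanCost}, \code{canonicalPresent}.
#' @slot finalPopulation Character matrix of the final genotypes (one per
#'   row).
#' @slot finalCosts Raw costs of the final population.
#' @slot bestGenotype Best raw-cost genotype seen in any generation.
#' @slot bestCost Its raw cost.
#' @exportClass RunRecord
setClass("RunRecord",
  representation(
    config = "GAConfig", seed = "integer", stats = "data.frame",
    finalPopulation = "matrix", finalCosts = "numeric",
    bestGenotype = "character", bestCost = "numeric"))

setValidity("RunRecord", function(object) {
  msg <- character(0)
  if (nrow(object@finalPopulation) != object@config@populationSize)
    msg <- c(msg, "final population size must equal populationSize")
  if (length(object@finalCosts) != nrow(object@finalPopulation))
    msg <- c(msg, "finalCosts length must match the population")
  if (any(object@stats$bestCost > object@stats$meanCost + 1e-12))
    msg <- c(msg, "bestCost must not exceed meanCost")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RunRecord", function(object) {
  fin <- object@stats[nrow(object@stats), ]
  cat(sprintf(
    "RunRecord (%s/%s, seed %d): %d generations\n final best %.4f, final mean %.4f, overall best %.4f\n",
    object@config@model, object@config@scheme, object@seed,
    max(object@stats$generation), fin$bestCost, fin$meanCost,
    object@bestCost))
})

#' Accessors for RunRecord objects
#'
#' \code{runStats} returns the per-generation statistics data.frame;
#' \code{finalPopulation} the final genotype matrix; \code{finalCosts}
#' their raw costs; \code{bestGenotype}/\code{bestCost} the best individual
#' seen across the whole run; \code{gaConfig} the configuration.
#'
#' @param x A \code{RunRecord}.
#' @return See individual descriptions.
#' @name RunRecord-accessors
#' @aliases runStats finalPopulation finalCosts bestGenotype bestCost
#'   gaConfig
NULL

#' @rdname RunRecord-accessors
#' @export
runStats <- function(x) x@stats

#' @rdname RunRecord-accessors
#' @export
finalPopulation <- function(x) x@finalPopulation

#' @rdname RunRecord-accessors
#' @export
finalCosts <- function(x) x@finalCosts

#' @rdname RunRecord-accessors
#' @export
bestGenotype <- function(x) x@bestGenotype

#' @rdname RunRecord-accessors
#' @export
bestCost <- function(x) x@bestCost

#' @rdname RunRecord-accessors
#' @export
gaConfig <- function(x) x@config
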
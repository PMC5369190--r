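# The GA engine. Populations are integer label matrices internally; each
# generation applies (1) optional fitness sharing on the selection costs,
# (2) tournament selection without replacement, (3) one swap per offspring
# with probability swapProb, (4) per-position mutation (unrestrictive model
# only), (5) elitism on raw costs. Statistics are always computed from raw
# costs.

#' Swap operator
#'
#' Exchanges the contents of two distinct, uniformly chosen genotype
#' positions. Works for both models: a restrictive permutation stays a
#' permutation, and an unrestrictive assignment keeps its three stop
#' positions (a swap may relocate a stop codon but never changes the label
#' multiset). Applying the same swap twice restores the genotype.
#'
#' @param g A genotype (character vector, length 20 or 64).
#' @return The swapped genotype.
#' @export
swapOperator <- function(g) {
  L <- length(g)
  p <- sample.int(L, 2L)
  g[p] <- g[rev(p)]
  g
}

#' Mutation operator (unrestrictive model)
#'
#' Visits the 64 positions in order; each position holding an amino acid is
#' mutated with probability \code{prob} to a uniformly chosen
#' \emph{different} amino acid (never to stop). Stop positions are never
#' touched, and a position whose amino acid is the sole representative of
#' that amino acid in the whole code is skipped, so all 20 amino acids stay
#' represented. Mutation is not defined for restrictive genotypes.
#'
#' @param g Unrestrictive genotype (length 64).
#' @param prob Per-position mutation probability.
#' @return The mutated genotype.
#' @export
mutationOperator <- function(g, prob) {
  if (length(g) != .N_CODONS)
    stop("mutation is defined only for unrestrictive genotypes")
  gi <- .toInternal(g)[1L, ]
  cnt <- tabulate(gi, .STOP_IDX)
  for (k in seq_len(.N_CODONS)) {
    a <- gi[k]
    if (a == .STOP_IDX || cnt[a] <= 1L) next
    if (runif(1) < prob) {
      r <- sample.int(.N_AA - 1L, 1L)
      b <- r + (r >= a)
      gi[k] <- b
      cnt[a] <- cnt[a] - 1L
      cnt[b] <- cnt[b] + 1L
    }
  }
  .genotypeFromInt(gi, "unrestrictive")
}

#' Tournament selection
#'
#' Samples \code{windowSize} distinct individuals uniformly and returns the
#' index of the one with the lowest cost; ties go to the lowest index.
#'
#' @param costs Selection costs (shared costs when sharing is active).
#' @param windowSize Tournament window (1 <= window <= length(costs)).
#' @return The selected index.
#' @export
tournamentSelect <- function(costs, windowSize) {
  n <- length(costs)
  if (windowSize < 1L || windowSize > n)
    stop("windowSize must lie in [1, population size]")
  cand <- sort(sample.int(n, windowSize))
  cand[which.min(costs[cand])]
}

# ---- internal vectorized generation step --------------------------------

# cfg here is a plain list extracted once from a GAConfig (slot access in
# the hot loop is measurable); pop is an integer matrix, costs its raw
# costs. Returns list(pop, costs, best, mean, canonicalPresent).
.stepInternal <- function(pop, costs, cfg) {
  n <- nrow(pop); L <- ncol(pop)
  selCosts <- costs
  if (!is.na(cfg$sigmaShare)) {
    d <- .distMatInternal(pop, cfg$scale)
    niche <- rowSums(ifelse(d < cfg$sigmaShare,
                            1 - (d / cfg$sigmaShare)^cfg$alpha, 0))
    selCosts <- costs * niche
  }
  # tournament selection, without replacement within each window
  win <- cfg$window
  cand <- vapply(seq_len(n), function(i) sample.int(n, win), integer(win))
  cand <- matrix(cand, nrow = win)
  cm <- matrix(selCosts[cand], nrow = win)
  sel <- cand[cbind(max.col(t(-cm), ties.method = "first"), seq_len(n))]
  newPop <- pop[sel, , drop = FALSE]
  # swap applications: "geometric" repeats while the swapProb coin keeps
  # firing (mean one swap at 0.5, enabling compound moves); "single" stops
  # after the first application
  active <- seq_len(n)
  repeat {
    fire <- active[runif(length(active)) < cfg$swapProb]
    if (length(fire)) {
      p1 <- sample.int(L, length(fire), replace = TRUE)
      p2 <- 1L + (p1 - 1L + sample.int(L - 1L, length(fire),
                                       replace = TRUE)) %% L
      i1 <- cbind(fire, p1); i2 <- cbind(fire, p2)
      tmp <- newPop[i1]; newPop[i1] <- newPop[i2]; newPop[i2] <- tmp
    }
    if (cfg$swapCount == "single" || !length(fire)) break
    active <- fire
  }
  # mutation (unrestrictive only): sequential over positions, vectorized
  # over individuals; the sole-representative rule is enforced against the
  # running counts so no amino acid can ever drop out
  if (cfg$model == "unrestrictive" && cfg$mutationProb > 0) {
    cnt <- matrix(0L, n, .N_AA)
    for (a in seq_len(.N_AA)) cnt[, a] <- rowSums(newPop == a)
    rows <- seq_len(n)
    for (k in seq_len(L)) {
      cur <- newPop[, k]
      if (cfg$mutationPerPosition) {
        fire <- runif(n) < cfg$mutationProb
      } else {
        # per-individual reading: one position drawn per individual
        fire <- cfg$mutPos == k
      }
      ok <- fire & cur != .STOP_IDX
      ok[ok] <- cnt[cbind(rows[ok], cur[ok])] > 1L
      if (any(ok)) {
        w <- which(ok)
        old <- cur[w]
        r <- sample.int(.N_AA - 1L, length(w), replace = TRUE)
        newa <- r + (r >= old)
        newPop[cbind(w, k)] <- newa
        cnt[cbind(w, old)] <- cnt[cbind(w, old)] - 1L
        cnt[cbind(w, newa)] <- cnt[cbind(w, newa)] + 1L
      }
    }
  }
  newCosts <- .populationCosts(newPop, cfg$model, cfg$scheme, cfg$scale)
  if (cfg$elitism) {
    bi <- which.min(costs)          # best RAW parent
    wi <- which.max(newCosts)       # worst RAW offspring
    newPop[wi, ] <- pop[bi, ]
    newCosts[wi] <- costs[bi]
  }
  list(pop = newPop, costs = newCosts,
       best = min(newCosts), mean = mean(newCosts),
       canonicalPresent = .containsGenotype(newPop, cfg$canonInt))
}

.containsGenotype <- function(popInt, gInt) {
  any(rowSums(popInt == rep(gInt, each = nrow(popInt))) == length(gInt))
}

.cfgAsList <- function(config) {
  list(model = config@model, scheme = config@scheme,
       mutationProb = config@mutationProb,
       mutationPerPosition = config@mutationPerPosition,
       swapProb = config@swapProb, swapCount = config@swapCount,
       window = max(1L, as.integer(round(config@tournamentFraction *
                                         config@populationSize))),
       sigmaShare = config@sigmaShare, alpha = config@alpha,
       elitism = config@elitism,
       scale = .POLAR_REQUIREMENT,
       canonInt = .toInternal(canonicalGenotype(config@model))[1L, ])
}

#' One GA generation step
#'
#' Advances a population by one generation under a configuration: optional
#' fitness sharing on the selection costs, tournament selection, swap and
#' (unrestrictive) mutation operators, then elitism on raw costs.
#' Statistics refer to the raw costs of the new population.
#'
#' @param pop Character matrix of genotypes, one per row.
#' @param rawCosts Raw costs of \code{pop} (recomputed if missing).
#' @param config A \code{\linkS4class{GAConfig}}.
#' @return List with \code{population} (character matrix),
#'   \code{rawCosts}, and \code{stats} (one-row data.frame:
#'   \code{bestCost}, \code{meanCost}, \code{canonicalPresent}).
#' @export
gaStep <- function(pop, rawCosts = NULL, config) {
  popInt <- .toInternal(pop)
  cfg <- .cfgAsList(config)
  if (!cfg$mutationPerPosition)
    cfg$mutPos <- ifelse(runif(nrow(popInt)) < cfg$mutationProb,
                         sample.int(ncol(popInt), nrow(popInt),
                                    replace = TRUE), 0L)
  if (is.null(rawCosts))
    rawCosts <- .populationCosts(popInt, cfg$model, cfg$scheme, cfg$scale)
  st <- .stepInternal(popInt, rawCosts, cfg)
  list(population = .toLabels(st$pop, config@model),
       rawCosts = st$costs,
       stats = data.frame(bestCost = st$best, meanCost = st$mean,
                          canonicalPresent = st$canonicalPresent))
}

#' Run the genetic algorithm
#'
#' Initializes a random population (optionally substituting the canonical
#' genotype for one random individual), steps it through
#' \code{config@generations} generations and records per-generation raw
#' statistics, the final population and the best genotype encountered. The
#' run is fully reproducible from \code{seed}.
#'
#' @param config A \code{\linkS4class{GAConfig}}.
#' @param seed Run seed; defaults to \code{config@rngSeed}.
#' @return A \code{\linkS4class{RunRecord}}.
#' @examples
#' cfg <- GAConfig(populationSize = 50L, generations = 5L, rngSeed = 11L)
#' rec <- runGA(cfg)
#' head(runStats(rec))
#' @export
runGA <- function(config, seed = config@rngSeed) {
  validObject(config)
  seed <- as.integer(seed)
  set.seed(seed)
  cfg <- .cfgAsList(config)
  n <- config@populationSize
  pop <- if (config@model == "restrictive") .randPermMat(n)
         else .randUnrestMat(n)
  if (config@seedCanonical)
    pop[sample.int(n, 1L), ] <- cfg$canonInt
  costs <- .populationCosts(pop, cfg$model, cfg$scheme, cfg$scale)
  G <- config@generations
  stats <- data.frame(
    generation = 0:G, bestCost = NA_real_, meanCost = NA_real_,
    canonicalPresent = NA)
  stats$bestCost[1] <- min(costs)
  stats$meanCost[1] <- mean(costs)
  stats$canonicalPresent[1] <- .containsGenotype(pop, cfg$canonInt)
  bi <- which.min(costs)
  bestG <- pop[bi, ]; bestC <- costs[bi]
  for (g in seq_len(G)) {
    if (!cfg$mutationPerPosition)
      cfg$mutPos <- ifelse(runif(n) < cfg$mutationProb,
                           sample.int(ncol(pop), n, replace = TRUE), 0L)
    st <- .stepInternal(pop, costs, cfg)
    pop <- st$pop; costs <- st$costs
    stats$bestCost[g + 1] <- st$best
    stats$meanCost[g + 1] <- st$mean
    stats$canonicalPresent[g + 1] <- st$canonicalPresent
    if (st$best < bestC) {
      bi <- which.min(costs)
      bestG <- pop[bi, ]; bestC <- costs[bi]
    }
  }
  new("RunRecord", config = config, seed = seed, stats = stats,
      finalPopulation = .toLabels(pop, config@model),
      finalCosts = costs,
      bestGenotype = .genotypeFromInt(bestG, config@model),
      bestCost = bestC)
}

#' Multiple independent GA runs
#'
#' Executes \code{config@nRuns} runs with distinct per-run seeds derived
#' deterministically from the master seed (\code{set.seed(rngSeed)}
#' followed by \code{sample.int(.Machine$integer.max, nRuns)}), and
#' aggregates the final-generation statistics.
#'
#' @param config A \code{\linkS4class{GAConfig}}.
#' @return List with \code{records} (list of \code{RunRecord}) and
#'   \code{aggregate}, the \code{\link{summarizeEnsemble}} table.
#' @export
multiRun <- function(config) {
  validObject(config)
  set.seed(config@rngSeed)
  seeds <- sample.int(.Machine$integer.max, config@nRuns)
  records <- lapply(seeds, function(s) runGA(config, seed = s))
  list(records = records, aggregate = summarizeEnsemble(records))
}
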
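# Fitness sharing: pairwise code distance in polar-requirement space, the
# triangular sharing function, shared costs for minimization, and the two
# real-parameter benchmark functions used to demonstrate niching behavior.

#' Pairwise distance between two codes
#'
#' Root squared deviation of the polar requirements encoded at aligned
#' genotype positions, normalized by the maximum possible deviation
#' \eqn{Max\_RSD = \sqrt{L\,(13.0-4.8)^2}} so distances lie in [0, 1].
#' \code{L} is the genotype length (20 restrictive, 64 unrestrictive). For
#' unrestrictive codes, positions where either code encodes the stop signal
#' are skipped in the sum, but \code{L} in the normalization stays 64.
#'
#' @param a,b Genotypes of the same model (length 20 or 64 character
#'   vectors).
#' @param scale Property scale.
#' @return A number in [0, 1].
#' @examples
#' g <- canonicalGenotype("restrictive")
#' codeDistance(g, g)  # 0
#' @export
codeDistance <- function(a, b, scale = polarRequirement()) {
  if (length(a) != length(b))
    stop("codes of different models cannot be compared")
  x <- c(unname(scale[.AA]), NA_real_)
  xa <- x[.toInternal(a)[1L, ]]
  xb <- x[.toInternal(b)[1L, ]]
  keep <- !is.na(xa) & !is.na(xb)
  rng <- max(scale) - min(scale)
  sqrt(sum((xa[keep] - xb[keep])^2)) / (sqrt(length(a)) * rng)
}

# full pairwise distance matrix of an integer population matrix; the
# stop-masked squared deviations are expanded into three matrix products:
#   sum_k M_ik M_jk (X_ik - X_jk)^2 = S M' + M S' - 2 Y Y'
# with Y = X masked to 0 at stops, M the presence indicator, S = Y*Y.
.distMatInternal <- function(popInt, scale = .POLAR_REQUIREMENT) {
  n <- nrow(popInt); L <- ncol(popInt)
  x <- c(unname(scale[.AA]), NA_real_)
  X <- matrix(x[popInt], n, L)
  M <- 1 - is.na(X)
  Y <- X; Y[is.na(Y)] <- 0
  S <- Y * Y
  D2 <- S %*% t(M) + M %*% t(S) - 2 * tcrossprod(Y)
  D2[D2 < 0] <- 0                       # floating-point guard
  d <- sqrt(D2) / (sqrt(L) * (max(scale) - min(scale)))
  diag(d) <- 0
  d
}

#' Distance matrix of a code population
#'
#' Computes all pairwise \code{\link{codeDistance}} values of a population
#' (one genotype per row) as a symmetric matrix with zero diagonal.
#'
#' @param pop Character matrix of genotypes (n x 20 or n x 64).
#' @param scale Property scale.
#' @return n x n numeric matrix with entries in [0, 1].
#' @export
distanceMatrix <- function(pop, scale = polarRequirement()) {
  .distMatInternal(.toInternal(pop), scale)
}

#' Sharing function
#'
#' The triangular (for \code{alpha = 1}) sharing kernel:
#' \code{1 - (d / sigmaShare)^alpha} for \code{d < sigmaShare}, 0 otherwise.
#' Vectorized over \code{d}.
#'
#' @param d Nonnegative distance(s).
#' @param sigmaShare Sharing radius (> 0).
#' @param alpha Sharing level (> 0, default 1).
#' @return Value(s) in [0, 1].
#' @examples
#' sharingValue(c(0, 0.05, 0.1, 0.2), sigmaShare = 0.1)
#' @export
sharingValue <- function(d, sigmaShare, alpha = 1) {
  stopifnot(sigmaShare > 0, alpha > 0, all(d >= 0))
  ifelse(d < sigmaShare, 1 - (d / sigmaShare)^alpha, 0)
}

#' Shared costs of a population
#'
#' For a minimization problem the shared cost multiplies the raw cost by
#' the niche count: \code{shared[i] = cost[i] * sum_j sh(d[i,j])}, the sum
#' running over all individuals including \code{i} itself (so an isolated
#' individual keeps its raw cost, and a crowded one is penalized).
#'
#' @param costs Raw costs (length n).
#' @param dmat n x n distance matrix.
#' @param sigmaShare Sharing radius.
#' @param alpha Sharing level.
#' @return Numeric vector of shared costs, elementwise >= \code{costs} for
#'   nonnegative costs.
#' @export
sharedCosts <- function(costs, dmat, sigmaShare, alpha = 1) {
  if (length(costs) != nrow(dmat) || nrow(dmat) != ncol(dmat))
    stop("costs length must match the distance matrix dimension")
  niche <- rowSums(ifelse(dmat < sigmaShare,
                          1 - (dmat / sigmaShare)^alpha, 0))
  costs * niche
}

# ---- real-parameter niching benchmarks ----------------------------------

#' Five-peak niching benchmark
#'
#' The classical multimodal benchmark with five unequally spaced maxima of
#' decreasing height on [0, 1]:
#' \deqn{f(x) = e^{-2\ln 2\,((x-0.08)/0.854)^2}\,\sin^6\!\big(5\pi(x^{3/4}-0.05)\big)}
#' Local maxima sit near x = 0.080, 0.247, 0.451, 0.681 and 0.934, the
#' first being the global maximum.
#'
#' @param x Numeric vector in [0, 1].
#' @return Function values in [0, 1].
#' @examples
#' fivePeakFunction(0.08)  # ~ 1, the global peak
#' @export
fivePeakFunction <- function(x) {
  if (any(x < 0 | x > 1)) stop("fivePeakFunction is defined on [0, 1]")
  exp(-2 * log(2) * ((x - 0.08) / 0.854)^2) *
    sin(5 * pi * (x^0.75 - 0.05))^6
}

#' Unimodal parabola benchmark
#'
#' \code{1 + x^2} on [-1, 1]: a toy minimization target whose single
#' optimum shows how sharing spreads a population around a minimum instead
#' of collapsing onto it.
#'
#' @param x Numeric vector.
#' @return \code{1 + x^2}.
#' @export
parabolaFunction <- function(x) 1 + x^2

#' Real-parameter GA demo with optional fitness sharing
#'
#' A minimal one-dimensional genetic algorithm (tournament selection and a
#' per-individual perturbation mutation) used to visualize the effect of
#' fitness sharing on the two benchmark functions. Sharing uses the raw
#' parameter distance |x_i - x_j|; for maximization the shared fitness
#' divides by the niche count, for minimization it multiplies. Because
#' tournament selection reacts too slowly to crowding for the classical
#' parent-population sharing to protect small niches, the demo uses
#' continuously updated sharing: each tournament evaluates niche counts
#' against the offspring population built so far, which keeps all peaks
#' stably occupied with numbers proportional to their height. No elitism
#' is applied.
#'
#' @param fn Objective function of one numeric vector argument.
#' @param lower,upper Domain bounds.
#' @param maximize Optimization direction.
#' @param populationSize,generations GA size parameters.
#' @param mutationProb Per-individual probability of perturbing x.
#' @param mutationWidth Half-width of the uniform perturbation (clipped to
#'   the domain); small relative to the inter-peak spacing so mutation
#'   explores within a niche rather than between niches.
#' @param tournamentFraction Tournament window as a fraction of the
#'   population (window >= 1).
#' @param sigmaShare Sharing radius; \code{NA} disables sharing.
#' @param alpha Sharing level.
#' @return A data.frame of the final population: columns \code{x},
#'   \code{value}. Uses R's global RNG.
#' @examples
#' set.seed(2)
#' final <- runRealGA(fivePeakFunction, 0, 1, sigmaShare = 0.1)
#' range(final$value)
#' @export
runRealGA <- function(fn, lower, upper, maximize = TRUE,
                      populationSize = 100L, generations = 100L,
                      mutationProb = 0.25, mutationWidth = 0.02,
                      tournamentFraction = 0.03,
                      sigmaShare = NA_real_, alpha = 1) {
  n <- populationSize
  win <- max(1L, as.integer(round(tournamentFraction * n)))
  x <- runif(n, lower, upper)
  f <- fn(x)
  sgn <- if (maximize) 1 else -1
  for (g in seq_len(generations)) {
    if (is.na(sigmaShare)) {
      cand <- matrix(vapply(seq_len(n), function(i) sample.int(n, win),
                            integer(win)), nrow = win)
      cm <- matrix(sgn * f[cand], nrow = win)
      sel <- cand[cbind(max.col(t(cm), ties.method = "first"), seq_len(n))]
      x <- x[sel]
    } else {
      newx <- numeric(n)
      for (i in seq_len(n)) {
        cand <- sample.int(n, win)
        nc <- if (i == 1L) rep(1, win) else
          vapply(cand, function(j) {
            dd <- abs(x[j] - newx[seq_len(i - 1L)])
            1 + sum(ifelse(dd < sigmaShare, 1 - (dd / sigmaShare)^alpha, 0))
          }, numeric(1))
        sf <- if (maximize) f[cand] / nc else f[cand] * nc
        newx[i] <- x[cand[which.max(sgn * sf)]]
      }
      x <- newx
    }
    mut <- runif(n) < mutationProb
    x[mut] <- pmin(upper, pmax(lower,
      x[mut] + runif(sum(mut), -mutationWidth, mutationWidth)))
    f <- fn(x)
  }
  data.frame(x = x, value = f)
}
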
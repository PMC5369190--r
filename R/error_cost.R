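# MS/tMS error cost of a code: the mean squared change in polar requirement
# over all single-base substitutions of all 64 codons, excluding events
# from or to stop codons and including synonymous events.  The tMS variant
# weights each event by its codon position and transition/transversion
# class; the weighted event count is used in the denominator so that the
# measure stays a weighted mean (it reduces exactly to the unweighted
# formula when all weights are 1).

#' Substitution weight schemes
#'
#' Per-event weights by codon position (rows 1-3) and mutation class
#' (columns \code{ts} = transition, \code{tv} = transversion). The
#' \code{"ms"} scheme weights all events equally; \code{"tms"} encodes the
#' empirical mistranslation/transition biases: position 1 (1, 0.5),
#' position 2 (0.5, 0.1), position 3 (1, 1) - the second codon base is the
#' best protected and its errors are almost exclusively transitional, while
#' the third position shows essentially no bias.
#'
#' @param scheme \code{"ms"} or \code{"tms"}.
#' @return A 3 x 2 numeric matrix with columns \code{ts}, \code{tv}.
#' @examples
#' weightScheme("tms")
#' @export
weightScheme <- function(scheme = c("ms", "tms")) {
  scheme <- match.arg(scheme)
  w <- if (scheme == "ms") matrix(1, 3, 2)
       else rbind(c(1, 0.5), c(0.5, 0.1), c(1, 1))
  dimnames(w) <- list(paste0("pos", 1:3), c("ts", "tv"))
  w
}

# ---- raw event table -----------------------------------------------------

# All 64*9 = 576 single-base change events over the codon set, as parallel
# vectors: from/to codon index, codon position, transition flag.  Purely
# combinatorial - independent of any particular code.
.eventTable <- function() {
  if (is.null(.cache$events)) {
    from <- integer(0); to <- integer(0); pos <- integer(0); ts <- logical(0)
    for (b1 in 1:4) for (b2 in 1:4) for (b3 in 1:4) {
      i <- (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
      bs <- c(b1, b2, b3)
      for (p in 1:3) {
        for (nb in setdiff(1:4, bs[p])) {
          nbs <- bs; nbs[p] <- nb
          from <- c(from, i)
          to <- c(to, (nbs[1] - 1L) * 16L + (nbs[2] - 1L) * 4L + nbs[3])
          pos <- c(pos, p)
          # bases 1,2 = U,C (pyrimidines); 3,4 = A,G (purines)
          ts <- c(ts, (bs[p] <= 2) == (nb <= 2))
        }
      }
    }
    .cache$events <- list(from = from, to = to, pos = pos, ts = ts)
  }
  .cache$events
}

# per-event weights under a scheme, aligned with .eventTable()
.eventWeights <- function(scheme) {
  key <- paste0("w_", scheme)
  if (is.null(.cache[[key]])) {
    ev <- .eventTable()
    w <- weightScheme(scheme)
    .cache[[key]] <- w[cbind(ev$pos, ifelse(ev$ts, 1L, 2L))]
  }
  .cache[[key]]
}

#' Enumerate the substitution events of a code
#'
#' Lists every single-base change over the 64 codons of a code (9 per
#' codon, 576 in total), dropping events whose source or target codon
#' encodes the stop signal. Synonymous events (same amino acid before and
#' after) are retained: they contribute zero cost but count in the
#' denominator of the error measure.
#'
#' @param code A codon->label map (named character vector of length 64) or
#'   a restrictive genotype (length 20, expanded automatically).
#' @return A data.frame with columns \code{from}, \code{to} (codons),
#'   \code{position} (1-3), \code{class} (\code{"transition"} /
#'   \code{"transversion"}), \code{fromLabel}, \code{toLabel}.
#' @examples
#' ev <- substitutionEvents(canonicalCode())
#' nrow(ev)  # 576 minus the events touching the three stop codons
#' @export
substitutionEvents <- function(code) {
  code <- .asCodonMap(code)
  ev <- .eventTable()
  fl <- unname(code[ev$from]); tl <- unname(code[ev$to])
  keep <- fl != .STOP & tl != .STOP
  cods <- .codons()
  data.frame(
    from = cods[ev$from[keep]], to = cods[ev$to[keep]],
    position = ev$pos[keep],
    class = ifelse(ev$ts[keep], "transition", "transversion"),
    fromLabel = fl[keep], toLabel = tl[keep],
    stringsAsFactors = FALSE)
}

# coerce a code argument (20-position genotype or 64-codon map) to a
# validated codon->label map in fixed codon order
.asCodonMap <- function(code) {
  if (length(code) == .N_AA) return(expandCode(code))
  if (length(code) != .N_CODONS)
    stop("a code must have 20 (restrictive genotype) or 64 (codon map) positions")
  if (!is.null(names(code))) {
    if (!identical(sort(names(code)), sort(.codons())))
      stop("invalid code: codon names do not match the 64 RNA codons")
    code <- code[.codons()]
  } else names(code) <- .codons()
  code
}

#' MS / tMS error cost of a code
#'
#' The weighted mean squared change in an amino acid property (polar
#' requirement by default) over all single-base substitutions of the code.
#' Events from or to stop codons are excluded; synonymous events are
#' included. Each retained event contributes its weight both to the
#' numerator (times the squared property difference) and to the
#' denominator, so the measure is a weighted mean; with the \code{"ms"}
#' scheme this is the plain average over included events.
#'
#' @param code Codon->label map (length 64) or restrictive genotype
#'   (length 20). Labels must be known to \code{scale} or be \code{"*"}.
#' @param scheme Weight scheme name, see \code{\link{weightScheme}}.
#' @param scale Named numeric property scale; defaults to
#'   \code{\link{polarRequirement}()}.
#' @return A single nonnegative number.
#' @examples
#' round(msError(canonicalCode(), "ms"), 2)   # 5.19
#' round(msError(canonicalCode(), "tms"), 2)  # 2.63
#' @export
msError <- function(code, scheme = c("ms", "tms"),
                    scale = polarRequirement()) {
  scheme <- match.arg(scheme)
  code <- .asCodonMap(code)
  if (!all(code %in% c(names(scale), .STOP)))
    stop("invalid code: labels not covered by the property scale")
  ev <- .eventTable()
  w <- .eventWeights(scheme)
  x <- unname(scale[code])                 # NA at stop codons
  xf <- x[ev$from]; xt <- x[ev$to]
  keep <- !is.na(xf) & !is.na(xt)
  sum(w[keep] * (xf[keep] - xt[keep])^2) / sum(w[keep])
}

# ---- vectorized population scoring --------------------------------------

# Restrictive model: events never touch the (fixed) stop block, so the cost
# of a permutation p is a quadratic form.  Aggregate the event weights into
# a 20x20 block matrix W[k,l] = total weight of events from block k to
# block l; then
#   cost(p) = [ sum_k X_k^2 (rowSums(W)+colSums(W))_k - 2 X' W X ] / sum(W)
# with X_k the property value of the amino acid p assigns to block k.
.restrictiveEngine <- function(scheme) {
  key <- paste0("rest_", scheme)
  if (is.null(.cache[[key]])) {
    ev <- .eventTable()
    w <- .eventWeights(scheme)
    bi <- .blockIndex()
    fb <- bi[ev$from]; tb <- bi[ev$to]
    keep <- fb != .STOP_IDX & tb != .STOP_IDX
    W <- matrix(0, .N_AA, .N_AA)
    idx <- cbind(fb[keep], tb[keep])
    for (r in seq_len(nrow(idx)))
      W[idx[r, 1], idx[r, 2]] <- W[idx[r, 1], idx[r, 2]] + w[keep][r]
    .cache[[key]] <- list(W = W, s = rowSums(W) + colSums(W), tot = sum(W))
  }
  .cache[[key]]
}

# costs of restrictive permutations (integer matrix, one per row)
.restrictiveCosts <- function(permMat, scheme, scale = .POLAR_REQUIREMENT) {
  eng <- .restrictiveEngine(scheme)
  x <- unname(scale[.AA])
  P <- matrix(x[permMat], nrow(permMat), .N_AA)
  as.vector(P^2 %*% eng$s - 2 * rowSums((P %*% eng$W) * P)) / eng$tot
}

# costs of unrestrictive assignments (integer matrix, 21 = stop, one per
# row); stop placement varies so both numerator and the weighted event
# count must be evaluated per individual
.unrestrictiveCosts <- function(labMat, scheme, scale = .POLAR_REQUIREMENT) {
  ev <- .eventTable()
  w <- .eventWeights(scheme)
  x <- c(unname(scale[.AA]), NA_real_)
  X <- matrix(x[labMat], nrow(labMat), .N_CODONS)
  D <- (X[, ev$from, drop = FALSE] - X[, ev$to, drop = FALSE])^2
  pres <- !is.na(D)
  D[!pres] <- 0
  as.vector(D %*% w) / as.vector(pres %*% w)
}

# dispatch on model
.populationCosts <- function(popInt, model, scheme,
                             scale = .POLAR_REQUIREMENT) {
  if (model == "restrictive") .restrictiveCosts(popInt, scheme, scale)
  else .unrestrictiveCosts(popInt, scheme, scale)
}

# ---- p.d.m. and random-code statistics ----------------------------------

#' Percentage distance minimization
#'
#' Places a code's error cost on a linear scale between the mean cost of
#' random codes (0%) and the best known cost (100%):
#' \deqn{p.d.m. = 100\,(\Delta_{mean} - \Delta_{code}) /
#'               (\Delta_{mean} - \Delta_{low}).}
#' Values above 100 or below 0 are possible for codes outside the
#' \eqn{[\Delta_{low}, \Delta_{mean}]} interval.
#'
#' @param deltaCode Cost of the code under study.
#' @param deltaMean Mean cost of random codes.
#' @param deltaLow Best (lowest) known cost.
#' @return The percentage as a single number.
#' @examples
#' pdm(6.5, 9, 4)  # 50
#' @export
pdm <- function(deltaCode, deltaMean, deltaLow) {
  if (deltaMean == deltaLow)
    stop("degenerate denominator: deltaMean equals deltaLow")
  (deltaMean - deltaCode) / (deltaMean - deltaLow) * 100
}

#' Random-code cost statistics
#'
#' Draws \code{n} random codes under a model, scores each with the chosen
#' scheme, and summarizes the sample: mean, standard deviation, and the
#' number of codes strictly more efficient (lower cost) than the canonical
#' code. This is the classical statistical assessment of code optimality;
#' with the restrictive model, the MS scheme and n = 1e6 the expected
#' count of better codes is of the order of 114 per million.
#'
#' @param model \code{"restrictive"} or \code{"unrestrictive"}.
#' @param scheme Weight scheme name.
#' @param n Sample size (>= 1).
#' @param scale Property scale.
#' @param chunkSize Codes scored per block, bounding memory use.
#' @param keepCosts If TRUE, the per-code costs are returned as well.
#' @return List with elements \code{mean}, \code{sd}, \code{countBetter},
#'   \code{canonicalCost}, \code{n}, \code{model}, \code{scheme} (and
#'   \code{costs} when requested). Uses R's global RNG.
#' @examples
#' set.seed(7)
#' s <- sampleRandomStatistics("restrictive", "ms", 1000)
#' s$mean > s$canonicalCost
#' @export
sampleRandomStatistics <- function(model = c("restrictive", "unrestrictive"),
                                   scheme = c("ms", "tms"), n,
                                   scale = polarRequirement(),
                                   chunkSize = 100000L,
                                   keepCosts = FALSE) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  stopifnot(n >= 1)
  canon <- msError(canonicalCode(), scheme, scale)
  tot <- 0; totsq <- 0; better <- 0L
  allCosts <- if (keepCosts) numeric(n) else NULL
  done <- 0L
  while (done < n) {
    k <- min(chunkSize, n - done)
    popInt <- if (model == "restrictive") .randPermMat(k) else .randUnrestMat(k)
    costs <- .populationCosts(popInt, model, scheme, scale)
    tot <- tot + sum(costs)
    totsq <- totsq + sum(costs^2)
    better <- better + sum(costs < canon)
    if (keepCosts) allCosts[(done + 1L):(done + k)] <- costs
    done <- done + k
  }
  m <- tot / n
  out <- list(
    mean = m,
    sd = if (n > 1) sqrt(max(0, (totsq - n * m^2) / (n - 1))) else 0,
    countBetter = better, canonicalCost = canon,
    n = as.integer(n), model = model, scheme = scheme)
  if (keepCosts) out$costs <- allCosts
  out
}
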
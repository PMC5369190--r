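# Hypothetical genetic code models: restrictive (amino acid permutations
# over the canonical codon blocks) and unrestrictive (free 64-codon
# assignments with exactly 3 stops and all 20 amino acids present).
#
# A single genotype is a named character vector of labels:
#   restrictive   - length 20, names = aminoAcids() (the block order),
#                   values a permutation of the 20 amino acids;
#   unrestrictive - length 64, names = codons in the fixed order, values
#                   one-letter codes or "*" (a full codon->label map).
# Populations are character matrices with one genotype per row. Internally
# the package works on integer label matrices (1..20 amino acids in
# aminoAcids() order, 21 = stop) for vectorized scoring.

.N_AA <- 20L
.N_CODONS <- 64L
.STOP_IDX <- 21L

# ---- internal integer representation ------------------------------------

.toInternal <- function(pop) {
  if (is.null(dim(pop))) pop <- matrix(pop, nrow = 1L)
  m <- match(pop, c(.AA, .STOP))
  dim(m) <- dim(pop)
  storage.mode(m) <- "integer"
  m
}

.toLabels <- function(popInt, model) {
  lab <- c(.AA, .STOP)[popInt]
  dim(lab) <- dim(popInt)
  colnames(lab) <- if (model == "restrictive") .AA else .codons()
  lab
}

.genotypeFromInt <- function(g, model) {
  stats::setNames(c(.AA, .STOP)[g],
                  if (model == "restrictive") .AA else .codons())
}

# n uniformly random 20-permutations, one per row
.randPermMat <- function(n) {
  t(vapply(seq_len(n), function(i) sample.int(.N_AA), integer(.N_AA)))
}

# n random unrestrictive assignments, one per row: 3 stop positions chosen
# uniformly, one guaranteed copy of each amino acid at 20 further uniform
# positions, remaining 41 positions i.i.d. uniform over the 20 amino acids
.randUnrestMat <- function(n) {
  t(vapply(seq_len(n), function(i) {
    g <- integer(.N_CODONS)
    idx <- sample.int(.N_CODONS)
    g[idx[1:3]] <- .STOP_IDX
    g[idx[4:23]] <- sample.int(.N_AA)
    g[idx[24:64]] <- sample.int(.N_AA, 41L, replace = TRUE)
    g
  }, integer(.N_CODONS)))
}

.checkModel <- function(model) {
  match.arg(model, c("restrictive", "unrestrictive"))
}

# ---- exported operations -------------------------------------------------

#' Random hypothetical codes
#'
#' \code{randomRestrictive} draws uniformly random permutations of the 20
#' amino acids over the canonical codon blocks. \code{randomUnrestrictive}
#' draws random 64-codon assignments with exactly three stop codons and at
#' least one codon per amino acid: the 3 stop positions are chosen uniformly
#' without replacement, one copy of each amino acid is placed at 20 further
#' uniformly chosen positions, and the remaining 41 positions are filled
#' i.i.d. uniformly over the 20 amino acids. Randomness comes from R's
#' global RNG; call \code{set.seed()} for reproducibility.
#'
#' @param n Number of codes to draw.
#' @return For \code{n = 1}, a single genotype (named character vector);
#'   otherwise a character matrix with one genotype per row.
#' @examples
#' set.seed(1)
#' randomRestrictive()
#' dim(randomUnrestrictive(5))
#' @export
randomRestrictive <- function(n = 1L) {
  m <- .randPermMat(n)
  if (n == 1L) .genotypeFromInt(m[1L, ], "restrictive")
  else .toLabels(m, "restrictive")
}

#' @rdname randomRestrictive
#' @export
randomUnrestrictive <- function(n = 1L) {
  m <- .randUnrestMat(n)
  if (n == 1L) .genotypeFromInt(m[1L, ], "unrestrictive")
  else .toLabels(m, "unrestrictive")
}

#' Expand a restrictive genotype to a full codon table
#'
#' Maps every codon of block \code{k} to the amino acid at position
#' \code{k} of the permutation; the stop block keeps \code{"*"}.
#'
#' @param g Restrictive genotype (character vector of length 20).
#' @return Named character vector of length 64 (codon -> label) in the
#'   fixed codon order.
#' @examples
#' ident <- setNames(aminoAcids(), aminoAcids())
#' identical(expandCode(ident), canonicalCode())
#' @export
expandCode <- function(g) {
  if (length(g) != .N_AA)
    stop("a restrictive genotype has exactly 20 positions")
  v <- validateCode(g, "restrictive")
  if (length(v)) stop("invalid restrictive genotype: ",
                      paste(v, collapse = ", "))
  stats::setNames(c(unname(g), .STOP)[.blockIndex()], .codons())
}

#' Canonical genotype under a code model
#'
#' The representation of the standard genetic code in each model's genotype
#' space: the identity permutation (restrictive) or the canonical codon
#' table itself (unrestrictive).
#'
#' @param model \code{"restrictive"} or \code{"unrestrictive"}.
#' @return Named character genotype.
#' @export
canonicalGenotype <- function(model = c("restrictive", "unrestrictive")) {
  model <- match.arg(model)
  if (model == "restrictive") stats::setNames(.AA, .AA) else canonicalCode()
}

#' Count the hypothetical codes of a model
#'
#' The restrictive model has exactly \eqn{20! = 2{,}432{,}902{,}008{,}176{,}640{,}000}
#' codes (about \eqn{2.43\times 10^{18}}). The unrestrictive code space is
#' not enumerated by this package and requesting it is an error.
#'
#' @param model Code model name.
#' @return The exact count as a double (20! is exactly representable).
#' @examples
#' countCodes("restrictive") / factorial(19)  # = 20
#' @export
countCodes <- function(model = c("restrictive", "unrestrictive")) {
  model <- match.arg(model)
  if (model != "restrictive")
    stop("the unrestrictive code space is not enumerated by this package")
  prod(seq_len(.N_AA))
}

#' Validate a hypothetical code
#'
#' Checks the structural invariants of a genotype or codon->label map and
#' returns the names of the violated ones (an empty character vector means
#' the code is valid). Length-20 inputs are checked as restrictive
#' genotypes (\code{"unknown_label"}, \code{"not_permutation"}); length-64
#' inputs as unrestrictive genotypes / codon maps (\code{"codon_names"},
#' \code{"unknown_label"}, \code{"stop_count"} for a stop-codon count other
#' than 3, \code{"missing_amino_acid"} if some amino acid has no codon).
#'
#' @param x Character vector of length 20 or 64.
#' @param model Optional model name; inferred from the length when omitted.
#' @return Character vector of violation names (possibly empty).
#' @examples
#' validateCode(canonicalCode())               # character(0)
#' g <- canonicalCode(); g["UAU"] <- "*"
#' validateCode(g)                             # "stop_count"
#' @export
validateCode <- function(x, model = NULL) {
  if (is.null(model)) {
    if (length(x) == .N_AA) model <- "restrictive"
    else if (length(x) == .N_CODONS) model <- "unrestrictive"
    else return("length")
  }
  model <- .checkModel(model)
  bad <- character(0)
  if (model == "restrictive") {
    if (length(x) != .N_AA) return("length")
    if (!all(x %in% .AA)) bad <- c(bad, "unknown_label")
    else if (anyDuplicated(x)) bad <- c(bad, "not_permutation")
  } else {
    if (length(x) != .N_CODONS) return("length")
    if (!is.null(names(x)) && !identical(sort(names(x)), sort(.codons())))
      bad <- c(bad, "codon_names")
    if (!all(x %in% c(.AA, .STOP))) bad <- c(bad, "unknown_label")
    else {
      if (sum(x == .STOP) != 3L) bad <- c(bad, "stop_count")
      if (!all(.AA %in% x)) bad <- c(bad, "missing_amino_acid")
    }
  }
  bad
}
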
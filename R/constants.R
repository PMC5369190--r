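# Built-in biological constants: the RNA codon set, the standard
# translation table, its block structure, and the polar requirement scale.

# RNA bases in the fixed order used throughout (U < C < A < G); codons are
# enumerated lexicographically under this order, third base fastest, which
# coincides with the presentation order of standard translation tables.
.BASES <- c("U", "C", "A", "G")

# 20 amino acids (one-letter codes) ordered alphabetically by their
# three-letter names: Ala Arg Asn Asp Cys Gln Glu Gly His Ile Leu Lys Met
# Phe Pro Ser Thr Trp Tyr Val.  This order defines the block order of
# codonBlocks() and hence the position semantics of restrictive genotypes.
.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.STOP <- "*"

# Woese polar requirement of the 20 amino acids (dimensionless partition
# coefficient in a water/pyridine system).  Extremes: Asp 13.0, Cys 4.8.
.POLAR_REQUIREMENT <- c(
  A = 7.0,  R = 9.1,  N = 10.0, D = 13.0, C = 4.8,
  Q = 8.6,  E = 12.5, G = 7.9,  H = 8.4,  I = 4.9,
  L = 4.9,  K = 10.1, M = 5.3,  F = 5.0,  P = 6.6,
  S = 7.5,  T = 6.6,  W = 5.2,  Y = 5.4,  V = 5.6
)

#' Amino acid alphabet
#'
#' The 20 standard amino acids in the fixed order used by the package
#' (alphabetical by three-letter name), and the stop label.
#'
#' @return For \code{aminoAcids()}, a character vector of 20 one-letter
#'   codes. For \code{stopLabel()}, the single character \code{"*"}.
#' @examples
#' aminoAcids()
#' stopLabel()
#' @export
aminoAcids <- function() .AA

#' @rdname aminoAcids
#' @export
stopLabel <- function() .STOP

#' Polar requirement scale
#'
#' Woese's polar requirement of the 20 amino acids, the single
#' physicochemical property from which both the substitution error cost and
#' the pairwise code distance are computed. Values range from 4.8 (Cys) to
#' 13.0 (Asp).
#'
#' @return Named numeric vector of length 20 (names are one-letter amino
#'   acid codes in \code{aminoAcids()} order).
#' @examples
#' range(polarRequirement())  # 4.8 (Cys) .. 13.0 (Asp)
#' @export
polarRequirement <- function() .POLAR_REQUIREMENT

# all 64 RNA codons, U<C<A<G lexicographic, third base fastest
.codons <- function() {
  if (is.null(.cache$codons)) {
    g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                     stringsAsFactors = FALSE)
    .cache$codons <- paste0(g$b1, g$b2, g$b3)
  }
  .cache$codons
}

#' The canonical genetic code
#'
#' The standard translation table as a named character vector: 64 RNA
#' codons (U<C<A<G lexicographic order) mapped to one-letter amino acid
#' codes, with \code{"*"} for the three stop codons UAA, UAG and UGA. The
#' table is taken from \code{Biostrings::GENETIC_CODE} (DNA bases
#' transliterated to RNA).
#'
#' @return Named character vector of length 64.
#' @examples
#' canonicalCode()[c("UUU", "UAA", "AUG")]
#' @export
canonicalCode <- function() {
  if (is.null(.cache$canonical)) {
    gc64 <- Biostrings::GENETIC_CODE
    cods <- .codons()
    .cache$canonical <- stats::setNames(
      unname(gc64[chartr("U", "T", cods)]), cods)
  }
  .cache$canonical
}

#' Codon block structure of the canonical code
#'
#' Partitions the 64 codons into the 21 synonymous blocks of the standard
#' genetic code: one block per amino acid (ordered alphabetically by
#' three-letter amino acid name, i.e. \code{aminoAcids()} order) followed by
#' the stop block \{UAA, UAG, UGA\}. Position \code{k} of a restrictive
#' genotype refers to block \code{k} of this list.
#'
#' @return Named list of 21 character vectors of codons; names are the 20
#'   one-letter codes then \code{"*"}.
#' @examples
#' lengths(codonBlocks())        # block degeneracies, sum to 64
#' codonBlocks()[["*"]]          # the stop block
#' @export
codonBlocks <- function() {
  if (is.null(.cache$blocks)) {
    cc <- canonicalCode()
    labs <- c(.AA, .STOP)
    .cache$blocks <- stats::setNames(
      lapply(labs, function(a) names(cc)[cc == a]), labs)
  }
  .cache$blocks
}

# block index (1..21, 21 = stop) of each codon, in codon order
.blockIndex <- function() {
  if (is.null(.cache$blockIdx)) {
    cc <- canonicalCode()
    .cache$blockIdx <- match(unname(cc), c(.AA, .STOP))
  }
  .cache$blockIdx
}
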
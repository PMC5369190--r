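# Text serialization of codes and populations.
#
# Code table format: 64 TSV lines "codon<TAB>label", codons in the fixed
# U<C<A<G lexicographic order, label = one-letter amino acid code or "*".
# Compact format: a single 64-character label string in the same codon
# order (20 characters for a restrictive genotype, in block order).
# Both round-trip exactly.

#' Read and write code tables
#'
#' \code{writeCodeTable} serializes a codon->label map (or a restrictive
#' genotype, which is expanded first) as 64 tab-separated
#' \code{codon<TAB>label} lines in the fixed codon order.
#' \code{readCodeTable} parses such a file, accepting codons in any order
#' but requiring each of the 64 exactly once and only known labels; the
#' returned map is in the fixed order.
#'
#' @param code Codon map (length 64) or restrictive genotype (length 20).
#' @param path File path.
#' @return \code{readCodeTable}: a named character vector of length 64;
#'   \code{writeCodeTable}: the path, invisibly.
#' @examples
#' f <- tempfile()
#' writeCodeTable(canonicalCode(), f)
#' identical(readCodeTable(f), canonicalCode())
#' @export
writeCodeTable <- function(code, path) {
  code <- .asCodonMap(code)
  writeLines(paste(names(code), unname(code), sep = "\t"), path)
  invisible(path)
}

#' @rdname writeCodeTable
#' @export
readCodeTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) != .N_CODONS)
    stop("malformed code table: expected 64 lines, found ", length(lines))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed code table: each line must be 'codon<TAB>label'")
  cods <- vapply(parts, `[`, character(1), 1L)
  labs <- vapply(parts, `[`, character(1), 2L)
  if (anyDuplicated(cods))
    stop("malformed code table: duplicate codon ",
         cods[duplicated(cods)][1L])
  if (!setequal(cods, .codons()))
    stop("malformed code table: codons do not cover the 64 RNA codons")
  bad <- setdiff(labs, c(.AA, .STOP))
  if (length(bad))
    stop("malformed code table: unknown label '", bad[1L], "'")
  stats::setNames(labs[match(.codons(), cods)], .codons())
}

#' Compact string form of a genotype
#'
#' \code{codeToString} collapses a genotype or codon map into a single
#' label string (64 characters in fixed codon order, or 20 characters in
#' block order for a restrictive genotype); \code{codeFromString} inverts
#' it. Round-trips are exact.
#'
#' @param code Genotype or codon map.
#' @param s A 20- or 64-character label string.
#' @return A character scalar / a named genotype vector.
#' @examples
#' s <- codeToString(canonicalCode())
#' nchar(s)
#' identical(codeFromString(s), canonicalCode())
#' @export
codeToString <- function(code) {
  if (length(code) == .N_CODONS) code <- .asCodonMap(code)
  else if (length(code) != .N_AA)
    stop("expected a 20-position genotype or a 64-codon map")
  paste(unname(code), collapse = "")
}

#' @rdname codeToString
#' @export
codeFromString <- function(s) {
  v <- strsplit(s, "")[[1L]]
  if (!length(v) %in% c(.N_AA, .N_CODONS))
    stop("expected a 20- or 64-character label string")
  if (!all(v %in% c(.AA, .STOP)))
    stop("unknown label in code string")
  if (length(v) == .N_AA) stats::setNames(v, .AA)
  else stats::setNames(v, .codons())
}

#' Read and write population snapshots
#'
#' A population file has one individual per line:
#' \code{compact_code<TAB>raw_cost}. Costs are written with 6 decimals.
#'
#' @param pop Character matrix of genotypes.
#' @param costs Raw costs, one per row of \code{pop}.
#' @param path File path.
#' @return \code{readPopulation}: list with \code{population} (character
#'   matrix) and \code{costs}; \code{writePopulation}: the path, invisibly.
#' @export
writePopulation <- function(pop, costs, path) {
  if (nrow(pop) != length(costs))
    stop("one cost per individual is required")
  strs <- apply(pop, 1L, paste, collapse = "")
  writeLines(sprintf("%s\t%.6f", strs, costs), path)
  invisible(path)
}

#' @rdname writePopulation
#' @export
readPopulation <- function(path) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  strs <- vapply(parts, `[`, character(1), 1L)
  costs <- as.numeric(vapply(parts, `[`, character(1), 2L))
  pop <- do.call(rbind, lapply(strs, function(s) unname(codeFromString(s))))
  colnames(pop) <- if (ncol(pop) == .N_AA) .AA else .codons()
  list(population = pop, costs = costs)
}
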
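# Independent brute-force oracle for the substitution error cost: explicit
# string-based enumeration of all 576 single-base change events, sharing no
# code with the package internals.

oracleBases <- c("U", "C", "A", "G")

oracleIsTransition <- function(b1, b2) {
  (b1 %in% c("A", "G") && b2 %in% c("A", "G")) ||
    (b1 %in% c("C", "U") && b2 %in% c("C", "U"))
}

# weights: 3x2 matrix, rows = codon position, cols = c(ts, tv)
oracleMsError <- function(codeMap, weights, scale) {
  num <- 0; den <- 0
  for (cd in names(codeMap)) {
    for (pos in 1:3) {
      b <- substring(cd, pos, pos)
      for (nb in setdiff(oracleBases, b)) {
        cd2 <- cd
        substring(cd2, pos, pos) <- nb
        a1 <- codeMap[[cd]]; a2 <- codeMap[[cd2]]
        if (a1 == "*" || a2 == "*") next
        w <- weights[pos, if (oracleIsTransition(b, nb)) 1L else 2L]
        num <- num + w * (scale[[a1]] - scale[[a2]])^2
        den <- den + w
      }
    }
  }
  num / den
}

# event count oracle: how many of the 576 raw events survive stop exclusion
oracleEventCount <- function(codeMap) {
  cnt <- 0L
  for (cd in names(codeMap)) {
    for (pos in 1:3) {
      b <- substring(cd, pos, pos)
      for (nb in setdiff(oracleBases, b)) {
        cd2 <- cd
        substring(cd2, pos, pos) <- nb
        if (codeMap[[cd]] != "*" && codeMap[[cd2]] != "*") cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# direct quadratic-free distance oracle (plain loop over positions)
oracleCodeDistance <- function(a, b, scale) {
  L <- length(a)
  ss <- 0
  for (k in seq_len(L)) {
    if (a[[k]] == "*" || b[[k]] == "*") next
    ss <- ss + (scale[[a[[k]]]] - scale[[b[[k]]]])^2
  }
  sqrt(ss) / sqrt(L * (13.0 - 4.8)^2)
}
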
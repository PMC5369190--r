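test_that("the canonical table has the standard structure", {
  cc <- canonicalCode()
  expect_length(cc, 64)
  expect_identical(sort(names(cc)[cc == "*"]), c("UAA", "UAG", "UGA"))
  expect_equal(sum(cc == "L"), 6)   # Leu: six codons
  expect_equal(sum(cc == "R"), 6)   # Arg: six codons
  expect_equal(length(unique(cc)), 21)
  expect_true(all(aminoAcids() %in% cc))
})

test_that("polar requirement extremes are Asp 13.0 and Cys 4.8", {
  pr <- polarRequirement()
  expect_length(pr, 20)
  expect_equal(unname(pr["D"]), 13.0)
  expect_equal(unname(pr["C"]), 4.8)
  expect_equal(names(which.max(pr)), "D")
  expect_equal(names(which.min(pr)), "C")
})

test_that("codon blocks partition the 64 codons", {
  bl <- codonBlocks()
  expect_length(bl, 21)
  expect_equal(sum(lengths(bl)), 64)
  expect_identical(sort(bl[["*"]]), c("UAA", "UAG", "UGA"))
  all64 <- unlist(bl, use.names = FALSE)
  expect_equal(anyDuplicated(all64), 0)   # disjoint
  expect_setequal(all64, names(canonicalCode()))
  # block order is alphabetical by three-letter name
  expect_identical(names(bl)[1:20], aminoAcids())
})

test_that("random restrictive genotypes are uniform permutations", {
  set.seed(101)
  for (i in 1:50)
    expect_length(validateCode(randomRestrictive(), "restrictive"), 0)
  # uniformity at position 1 over many draws (binomial 3 sd band)
  set.seed(102)
  pop <- randomRestrictive(10000)
  counts <- table(factor(pop[, 1], levels = aminoAcids()))
  expect_gt(chisq.test(counts)$p.value, 1e-4)
  expect_true(all(abs(counts / 10000 - 1 / 20) < 0.01))
  # determinism contract
  set.seed(7); a <- randomRestrictive()
  set.seed(7); b <- randomRestrictive()
  expect_identical(a, b)
})

test_that("random unrestrictive genotypes satisfy both constraints", {
  set.seed(103)
  pop <- randomUnrestrictive(2000)
  expect_equal(unname(rowSums(pop == "*")), rep(3, 2000))
  distinctAA <- apply(pop, 1, function(g) length(setdiff(unique(g), "*")))
  expect_equal(unname(distinctAA), rep(20L, 2000))
  # mean codons per amino acid = 61/20 by construction
  perAA <- sapply(aminoAcids(), function(a) mean(rowSums(pop == a)))
  expect_equal(mean(perAA), 61 / 20, tolerance = 1e-12)
  expect_true(all(abs(perAA - 3.05) < 0.15))
})

test_that("expansion maps blocks to permuted amino acids", {
  ident <- canonicalGenotype("restrictive")
  expect_identical(expandCode(ident), canonicalCode())
  # swapping Leu and Arg gives Leu the six Arg codons
  g <- ident
  g[c("L", "R")] <- c("R", "L")
  ex <- expandCode(g)
  expect_setequal(names(ex)[ex == "L"], codonBlocks()[["R"]])
  expect_setequal(names(ex)[ex == "R"], codonBlocks()[["L"]])
  # degeneracy conservation for random permutations
  set.seed(104)
  for (i in 1:20) {
    ex <- expandCode(randomRestrictive())
    expect_identical(sort(unname(table(ex))),
                     sort(unname(table(canonicalCode()))))
    expect_length(validateCode(ex), 0)
  }
})

test_that("code space counting", {
  expect_identical(countCodes("restrictive"), 2432902008176640000)
  expect_equal(countCodes("restrictive") / factorial(19), 20)
  expect_error(countCodes("unrestrictive"), "not enumerated")
})

test_that("validateCode names the violated invariant", {
  expect_length(validateCode(canonicalCode()), 0)
  g <- canonicalCode()
  g["UUU"] <- "*"
  expect_true("stop_count" %in% validateCode(g))
  r <- canonicalGenotype("restrictive")
  r[2] <- r[1]
  expect_identical(validateCode(r), "not_permutation")
  u <- canonicalCode()
  u[names(u) == "W"] <- "L"          # no-op guard; now break an amino acid
  u[u == "W"] <- "L"
  expect_true("missing_amino_acid" %in% validateCode(u))
  expect_identical(validateCode(c(A = "x")), "length")
})

test_that("serialization round-trips exactly", {
  tf <- tempfile()
  writeCodeTable(canonicalCode(), tf)
  expect_identical(readCodeTable(tf), canonicalCode())
  set.seed(105)
  u <- randomUnrestrictive()
  writeCodeTable(u, tf)
  expect_identical(readCodeTable(tf), u)
  expect_identical(codeFromString(codeToString(u)), u)
  r <- randomRestrictive()
  expect_identical(codeFromString(codeToString(r)), r)
  # malformed inputs are rejected with a named defect
  writeLines(readLines(tf)[-1], tf)
  expect_error(readCodeTable(tf), "64 lines")
  writeCodeTable(u, tf)
  ln <- readLines(tf); ln[5] <- "AAA\tZ"
  writeLines(ln, tf)
  expect_error(readCodeTable(tf), "unknown label|duplicate")
  # population snapshot round-trip
  set.seed(106)
  pop <- randomUnrestrictive(5)
  costs <- sapply(seq_len(5), function(i) msError(pop[i, ]))
  writePopulation(pop, costs, tf)
  back <- readPopulation(tf)
  expect_identical(back$population, pop)
  expect_equal(back$costs, costs, tolerance = 1e-6)
})
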
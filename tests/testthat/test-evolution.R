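smallCfg <- function(...) {
  args <- utils::modifyList(
    list(populationSize = 60L, generations = 10L, rngSeed = 5L, nRuns = 3L),
    list(...))
  do.call(GAConfig, args)
}

test_that("swap operator preserves type invariants and is an involution", {
  set.seed(401)
  g <- randomRestrictive()
  for (i in 1:200) {
    g2 <- swapOperator(g)
    expect_length(validateCode(g2, "restrictive"), 0)
    expect_equal(sum(g2 != g), 2)
  }
  u <- randomUnrestrictive()
  for (i in 1:200) {
    u2 <- swapOperator(u)
    expect_equal(sum(u2 == "*"), 3)
    expect_length(validateCode(u2, "unrestrictive"), 0)
  }
  # repeating the same pair restores the genotype
  set.seed(402); a <- swapOperator(g)
  set.seed(402); b <- swapOperator(a)
  expect_identical(b, g)
})

test_that("mutation operator keeps all amino acids and all stops", {
  set.seed(403)
  for (i in 1:100) {
    u <- randomUnrestrictive()
    m <- mutationOperator(u, 0.2)
    expect_equal(sum(m == "*"), 3)
    expect_length(setdiff(aminoAcids(), m), 0)
    expect_identical(which(m == "*"), which(u == "*"))  # stops untouched
  }
  u <- randomUnrestrictive()
  expect_identical(mutationOperator(u, 0), u)
  expect_error(mutationOperator(randomRestrictive(), 0.1), "unrestrictive")
  # prob 1 and every amino acid redundant: every amino-acid position moves
  u2 <- stats::setNames(c(rep(aminoAcids(), 3), "V", "*", "*", "*"),
                        names(canonicalCode()))
  expect_true(all(table(u2[u2 != "*"]) >= 2))
  set.seed(404)
  m2 <- mutationOperator(u2, 1)
  aaPos <- u2 != "*"
  expect_true(all(m2[aaPos] != u2[aaPos]))
  expect_length(setdiff(aminoAcids(), m2), 0)
})

test_that("tournament selection picks the window minimum", {
  expect_equal(tournamentSelect(c(1, 2), 2), 1)
  set.seed(405)
  costs <- runif(50)
  expect_equal(tournamentSelect(costs, 50), which.min(costs))
  # window 1 is uniform
  set.seed(406)
  picks <- replicate(2000, tournamentSelect(costs, 1))
  expect_gt(length(unique(picks)), 40)
  expect_error(tournamentSelect(costs, 51), "windowSize")
})

test_that("a generation step preserves validity and stats ordering", {
  set.seed(407)
  for (model in c("restrictive", "unrestrictive")) {
    cfg <- smallCfg(model = model)
    pop <- if (model == "restrictive") randomRestrictive(60)
           else randomUnrestrictive(60)
    st <- gaStep(pop, config = cfg)
    expect_equal(nrow(st$population), 60)
    for (i in 1:60)
      expect_length(validateCode(st$population[i, ], model), 0)
    expect_lte(st$stats$bestCost, st$stats$meanCost)
    # sharing-enabled step also preserves validity
    st2 <- gaStep(pop, config = smallCfg(model = model, sigmaShare = 0.1))
    for (i in 1:60)
      expect_length(validateCode(st2$population[i, ], model), 0)
  }
})

test_that("elitism makes the best raw cost non-increasing", {
  rec <- runGA(smallCfg(model = "restrictive", generations = 30L))
  expect_true(all(diff(runStats(rec)$bestCost) <= 1e-12))
  recU <- runGA(smallCfg(model = "unrestrictive", generations = 30L))
  expect_true(all(diff(runStats(recU)$bestCost) <= 1e-12))
  # sharing on: raw best still protected by raw-cost elitism
  recS <- runGA(smallCfg(model = "restrictive", generations = 30L,
                         sigmaShare = 0.1))
  expect_true(all(diff(runStats(recS)$bestCost) <= 1e-12))
})

test_that("runs are reproducible from the seed", {
  cfg <- smallCfg(model = "unrestrictive")
  a <- runGA(cfg); b <- runGA(cfg)
  expect_identical(runStats(a), runStats(b))
  expect_identical(finalPopulation(a), finalPopulation(b))
  expect_identical(bestGenotype(a), bestGenotype(b))
})

test_that("selection-only dynamics drift toward the initial best", {
  cfg <- GAConfig(populationSize = 80L, generations = 80L, swapProb = 0,
                  mutationProb = 0, tournamentFraction = 1.0,
                  rngSeed = 9L)
  rec <- runGA(cfg)
  st <- runStats(rec)
  # full-window tournament + no variation: uniform population at the
  # initial best within populationSize generations
  expect_equal(st$meanCost[nrow(st)], st$bestCost[1], tolerance = 1e-12)
  expect_equal(st$bestCost[nrow(st)], st$bestCost[1], tolerance = 1e-12)
})

test_that("every individual stays valid across a full small run", {
  cfg <- smallCfg(model = "unrestrictive", generations = 25L,
                  sigmaShare = 0.05)
  rec <- runGA(cfg)
  pop <- finalPopulation(rec)
  for (i in seq_len(nrow(pop)))
    expect_length(validateCode(pop[i, ], "unrestrictive"), 0)
  expect_equal(length(finalCosts(rec)), 60)
  expect_equal(min(finalCosts(rec)),
               runStats(rec)$bestCost[nrow(runStats(rec))])
})

test_that("multiRun derives distinct seeds and aggregates correctly", {
  cfg <- smallCfg(model = "restrictive")
  ens <- multiRun(cfg)
  expect_length(ens$records, 3)
  seeds <- vapply(ens$records, function(r) r@seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0)
  fin <- vapply(ens$records, function(r) {
    s <- runStats(r); s$bestCost[nrow(s)]
  }, numeric(1))
  expect_equal(ens$aggregate$mean[1], round(mean(fin), 2))
  # single run: sd exactly 0
  one <- multiRun(smallCfg(model = "restrictive", nRuns = 1L))
  expect_equal(one$aggregate$sd, c(0, 0))
})

test_that("canonical seeding places the canonical genotype in generation 0", {
  cfg <- smallCfg(model = "restrictive", seedCanonical = TRUE)
  rec <- runGA(cfg)
  expect_true(runStats(rec)$canonicalPresent[1])
  cfgU <- smallCfg(model = "unrestrictive", seedCanonical = TRUE)
  expect_true(runStats(runGA(cfgU))$canonicalPresent[1])
})

test_that("invalid configurations are rejected", {
  expect_error(GAConfig(populationSize = 1L))
  expect_error(GAConfig(swapProb = 1.5))
  expect_error(GAConfig(sigmaShare = -0.1))
  expect_error(GAConfig(model = "other"))
})
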
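test_that("code distance satisfies the metric axioms on random codes", {
  set.seed(301)
  for (i in 1:100) {
    a <- randomRestrictive(); b <- randomRestrictive()
    d <- codeDistance(a, b)
    expect_equal(codeDistance(a, a), 0)
    expect_equal(d, codeDistance(b, a))
    expect_true(d >= 0 && d <= 1)
  }
  for (i in 1:100) {
    a <- randomUnrestrictive(); b <- randomUnrestrictive()
    d <- codeDistance(a, b)
    expect_true(d >= 0 && d <= 1)
    expect_equal(d, codeDistance(b, a))
  }
  expect_error(codeDistance(randomRestrictive(), randomUnrestrictive()),
               "different models")
})

test_that("a two-position swap has the closed-form distance", {
  a <- canonicalGenotype("restrictive")
  b <- a
  b[c("D", "C")] <- c("C", "D")  # Asp <-> Cys, the extreme pair
  expect_equal(codeDistance(a, b), sqrt(2 * 8.2^2) / (8.2 * sqrt(20)))
  b2 <- a
  b2[c("L", "F")] <- c("F", "L")  # Leu 4.9 <-> Phe 5.0
  expect_equal(codeDistance(a, b2),
               sqrt(2 * (4.9 - 5.0)^2) / (8.2 * sqrt(20)))
})

test_that("distance matrix agrees with loop oracle and skips stops", {
  set.seed(302)
  popU <- randomUnrestrictive(15)
  dm <- distanceMatrix(popU)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 15))
  pr <- polarRequirement()
  for (i in 1:14) for (j in (i + 1):15)
    expect_equal(dm[i, j], oracleCodeDistance(popU[i, ], popU[j, ], pr),
                 tolerance = 1e-10)
  popR <- randomRestrictive(10)
  dmR <- distanceMatrix(popR)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(dmR[i, j], oracleCodeDistance(popR[i, ], popR[j, ], pr),
                 tolerance = 1e-10)
})

test_that("random restrictive pairs rarely exceed distance 0.6", {
  set.seed(303)
  a <- codeAdapt:::.randPermMat(10000)
  b <- codeAdapt:::.randPermMat(10000)
  x <- polarRequirement()[aminoAcids()]
  A <- matrix(x[a], 10000); B <- matrix(x[b], 10000)
  d <- sqrt(rowSums((A - B)^2)) / (8.2 * sqrt(20))
  expect_lt(quantile(d, 0.99), 0.65)
})

test_that("sharing function boundary identities", {
  expect_equal(sharingValue(0, 0.1), 1)
  expect_equal(sharingValue(0.1, 0.1), 0)
  expect_equal(sharingValue(0.25, 0.1), 0)
  expect_equal(sharingValue(0.05, 0.1, alpha = 1), 0.5)
  expect_equal(sharingValue(0.05, 0.1, alpha = 2), 0.75)
  # continuity at the radius
  eps <- 1e-9
  expect_lt(sharingValue(0.1 - eps, 0.1), 1e-6)
})

test_that("shared costs implement the multiplicative niche-count penalty", {
  # all pairs beyond the radius: niche count 1, costs unchanged
  d <- matrix(0.5, 4, 4); diag(d) <- 0
  costs <- c(1, 2, 3, 4)
  expect_equal(sharedCosts(costs, d, sigmaShare = 0.1), costs)
  # two identical individuals double each other's cost
  d2 <- matrix(0.5, 3, 3); diag(d2) <- 0; d2[1, 2] <- d2[2, 1] <- 0
  expect_equal(sharedCosts(c(1, 1, 5), d2, 0.1), c(2, 2, 5))
  # shared >= raw always (self term)
  set.seed(304)
  pop <- randomRestrictive(30)
  dm <- distanceMatrix(pop)
  raw <- runif(30, 1, 10)
  expect_true(all(sharedCosts(raw, dm, 0.2) >= raw - 1e-12))
  expect_error(sharedCosts(raw[-1], dm, 0.2), "dimension")
})

test_that("shared costs converge to raw costs as the radius shrinks", {
  set.seed(305)
  pop <- randomRestrictive(40)
  dm <- distanceMatrix(pop)
  raw <- runif(40, 1, 10)
  expect_equal(sharedCosts(raw, dm, 1e-9), raw)
})

test_that("the five-peak benchmark has the documented maxima", {
  grid <- seq(0, 1, by = 5e-4)
  f <- fivePeakFunction(grid)
  loc <- which(diff(sign(diff(f))) == -2) + 1
  peaks <- grid[loc]
  expect_length(peaks, 5)
  expect_equal(peaks, c(0.080, 0.247, 0.451, 0.681, 0.934), tolerance = 0.005 / 0.08)
  expect_true(all(abs(peaks - c(0.080, 0.247, 0.451, 0.681, 0.934)) < 0.005))
  # decreasing heights; global maximum at the first peak
  expect_true(all(diff(f[loc]) < 0))
  expect_equal(grid[which.max(f)], peaks[1])
  expect_error(fivePeakFunction(1.2), "defined on")
})

test_that("the parabola benchmark is the shifted square", {
  expect_equal(parabolaFunction(0), 1)
  expect_equal(parabolaFunction(1), 2)
  expect_equal(parabolaFunction(-1), 2)
  g <- seq(-1, 1, by = 0.05)
  expect_equal(parabolaFunction(g), parabolaFunction(-g))
})

test_that("sharing preserves niches on the five-peak demo", {
  peaks <- c(0.080, 0.247, 0.451, 0.681, 0.934)
  set.seed(306)
  withSh <- runRealGA(fivePeakFunction, 0, 1, maximize = TRUE,
                      sigmaShare = 0.1)
  occupied <- sapply(peaks, function(p) any(abs(withSh$x - p) < 0.02))
  expect_gte(sum(occupied), 4)
  set.seed(307)
  noSh <- runRealGA(fivePeakFunction, 0, 1, maximize = TRUE)
  expect_gte(mean(abs(noSh$x - peaks[1]) < 0.02), 0.9)
})

test_that("sharing spreads a minimizing population around the parabola optimum", {
  set.seed(308)
  noSh <- runRealGA(parabolaFunction, -1, 1, maximize = FALSE)
  set.seed(308)
  withSh <- runRealGA(parabolaFunction, -1, 1, maximize = FALSE,
                      sigmaShare = 0.1)
  expect_gt(sd(withSh$x), sd(noSh$x))
  expect_lt(mean(abs(noSh$x)), 0.05)
})
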
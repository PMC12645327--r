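test_that("flat likelihood gives log ML = 0 exactly for any step count", {
  phy <- simulateTimeTree(5, BirthDeathParams(1.5, 0, 1), 3, seed = 1)
  # all-missing characters carry likelihood exactly 1
  m <- TraitMatrix(matrix(NA_integer_, 5, 4,
    dimnames = list(phy$tip.label, paste0("c", 1:4))))
  for (K in c(2, 5)) {
    est <- steppingStoneLogML(m, steps = K, chainLength = 300,
      seed = 3, fixedTree = phy,
      hyper = list(estimateBD = FALSE, rootMax = 5))
    expect_equal(est@logML, 0, tolerance = 1e-12)
    expect_equal(est@sd, 0, tolerance = 1e-12)
  }
})

test_that("stepping-stone matches dense quadrature on a one-parameter toy", {
  phy <- simulateTimeTree(6, BirthDeathParams(1.5, 0, 1), 3, seed = 4)
  m <- simulateCovarionMatrix(phy, CovarionModel(overallRate = 0.3),
    c("1" = 40), seed = 5)
  est <- steppingStoneLogML(m, CovarionModel(overallRate = 0.3),
    fixedTree = phy, steps = 12, chainLength = 1500, seed = 2,
    freeParams = "rate", hyper = list(estimateBD = FALSE, rootMax = 10))
  # quadrature oracle: the only free parameter is the overall rate with an
  # Exp(1) prior; integrate the likelihood on a dense grid
  llfun <- function(r) totalLogLikelihood(m, phy,
    CovarionModel(freq = c(0.5, 0.5), alpha = 0.5, switchRate = 0.5,
      overallRate = r))
  grid <- seq(1e-4, 8, length.out = 3000)
  lp <- vapply(grid, function(r) llfun(r) + stats::dexp(r, 1, log = TRUE), 0)
  mx <- max(lp)
  quad <- mx + log(sum(exp(lp - mx)) * (grid[2] - grid[1]))
  expect_lt(abs(est@logML - quad), 3 * est@sd + 0.05)
  expect_error(steppingStoneLogML(m, steps = 1), "2 steps")
})

test_that("widening a data-informed prior lowers the marginal likelihood", {
  phy <- simulateTimeTree(6, BirthDeathParams(1.5, 0, 1), 3, seed = 4)
  m <- simulateCovarionMatrix(phy, CovarionModel(overallRate = 0.3),
    c("1" = 40), seed = 5)
  quadAt <- function(priorMean) {
    llfun <- function(r) totalLogLikelihood(m, phy,
      CovarionModel(overallRate = r))
    grid <- seq(1e-4, 12, length.out = 3000)
    lp <- vapply(grid, function(r)
      llfun(r) + stats::dexp(r, 1 / priorMean, log = TRUE), 0)
    mx <- max(lp)
    mx + log(sum(exp(lp - mx)) * (grid[2] - grid[1]))
  }
  # Occam factor: doubling the prior scale away from the data-supported
  # region wastes prior mass and must lower the marginal likelihood
  expect_gt(quadAt(0.5), quadAt(1))
  est1 <- steppingStoneLogML(m, CovarionModel(overallRate = 0.3),
    fixedTree = phy, steps = 10, chainLength = 1200, seed = 6,
    freeParams = "rate",
    hyper = list(estimateBD = FALSE, rootMax = 10, rateMean = 0.5))
  est2 <- steppingStoneLogML(m, CovarionModel(overallRate = 0.3),
    fixedTree = phy, steps = 10, chainLength = 1200, seed = 7,
    freeParams = "rate",
    hyper = list(estimateBD = FALSE, rootMax = 10, rateMean = 1))
  expect_gt(est1@logML, est2@logML)
})

test_that("more stepping stones reduce replicate variance", {
  phy <- simulateTimeTree(6, BirthDeathParams(1.5, 0, 1), 3, seed = 4)
  m <- simulateCovarionMatrix(phy, CovarionModel(overallRate = 0.3),
    c("1" = 30), seed = 5)
  run <- function(K, seed) steppingStoneLogML(m,
    CovarionModel(overallRate = 0.3), fixedTree = phy, steps = K,
    chainLength = 250, seed = seed, freeParams = "rate",
    hyper = list(estimateBD = FALSE, rootMax = 10), bootstrap = 10)@logML
  v2 <- var(vapply(1:10, function(s) run(2, s), 0))
  v16 <- var(vapply(1:10, function(s) run(16, s), 0))
  expect_lt(v16, v2)
})

test_that("Kass-Raftery interpretation maps magnitudes and signs", {
  expect_match(interpretLogBF(0.5), "negligible")
  expect_match(interpretLogBF(135), "decisive")
  expect_match(interpretLogBF(135), "separate phylogenies")
  expect_match(interpretLogBF(-4), "strong")
  expect_match(interpretLogBF(-4), "shared phylogeny")
  expect_match(interpretLogBF(2), "positive")
  expect_error(interpretLogBF(Inf), "finite")
})

test_that("a dataset against a bit-identical copy favours the shared tree, reproducibly", {
  sim <- simulatePairedDatasets(8, 60, sameTree = TRUE,
    model = CovarionModel(overallRate = 0.2),
    treePrior = BirthDeathParams(1.5, 0.25, 1), rootMax = 3, seed = 31)
  a <- sim$a
  b <- TraitMatrix(traitStates(a))  # bit-identical copy, same taxa
  tm <- data.frame(a = taxa(a), b = taxa(b))
  run <- function() sharedTreeBayesFactor(a, b, tm,
    model = CovarionModel(overallRate = 0.2),
    treePrior = BirthDeathParams(1.5, 0.25, 1), steps = 5,
    chainLength = 600, seed = 11, hyper = list(rootMax = 3))
  bf1 <- run()
  expect_lte(bf1@logBF, 0 + 3 * (bf1@sdA + bf1@sdB))
  expect_identical(run()@logBF, bf1@logBF)  # bit-for-bit reproducible
  expect_equal(bf1@logBF, bf1@logMLB - bf1@logMLA)
})
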
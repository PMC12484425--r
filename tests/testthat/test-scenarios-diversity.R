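# Counterfactual scenarios, diversity metrics and trend maps.

scenarioFixture <- function() {
  cov <- trendNoiseCovariates(1, nCells = 6, nYears = 7)
  # hand-set one cell's climate to the worked example
  cov$clim_gdd[cov$cell == 1] <- c(1, 2, 3, 4, 5, 9, 9)
  cov
}

test_that("the habitat-only scenario fixes climate at the first-5-year mean", {
  cov <- scenarioFixture()
  hab <- buildScenario(cov, "habitat_only")
  expect_equal(hab$clim_gdd[hab$cell == 1], rep(3, 7))  # mean of 1..5
  # habitat columns untouched
  expect_equal(hab$hab_conifer, cov$hab_conifer)
  # full is the identity
  expect_identical(buildScenario(cov, "full"), cov)
})

test_that("constant drivers make their scenario equal to the full covariates", {
  cov <- trendNoiseCovariates(2, nCells = 5, nYears = 7)
  # constant habitat across years: climate-only == full
  for (v in grep("^hab_|^comp_", names(cov), value = TRUE))
    cov[[v]] <- ave(cov[[v]], cov$cell)
  expect_equal(buildScenario(cov, "climate_only"), cov)
  # constant climate across years: habitat-only == full
  cov2 <- trendNoiseCovariates(3, nCells = 5, nYears = 7)
  for (v in grep("^clim_", names(cov2), value = TRUE))
    cov2[[v]] <- ave(cov2[[v]], cov2$cell)
  expect_equal(buildScenario(cov2, "habitat_only"), cov2)
})

test_that("scenario construction is idempotent and guards its baseline", {
  cov <- scenarioFixture()
  once <- buildScenario(cov, "habitat_only")
  expect_equal(buildScenario(once, "habitat_only"), once)
  onceC <- buildScenario(cov, "climate_only")
  expect_equal(buildScenario(onceC, "climate_only"), onceC)
  short <- cov[cov$year <= 2002, ]  # 5 years only
  expect_error(buildScenario(short, "habitat_only"), "baseline")
})

test_that("expected richness is the sum of occurrence probabilities", {
  expect_equal(expectedRichness(rep(1, 9)), 9)
  expect_equal(expectedRichness(rep(0, 9)), 0)
  expect_equal(expectedRichness(rep(0.5, 10)), 5)
  p <- matrix(runif(12), 3, 4)
  expect_equal(expectedRichness(p), rowSums(p))
  # raising any probability never lowers expected richness
  p2 <- p; p2[2, 3] <- min(1, p2[2, 3] + 0.2)
  expect_gte(expectedRichness(p2)[2], expectedRichness(p)[2])
})

test_that("Hill-Simpson evenness matches closed forms and bounds", {
  expect_equal(hillSimpsonEvenness(rep(2, 4)), 1)
  expect_equal(hillSimpsonEvenness(c(1, 0, 0, 0)), 0.25)
  expect_equal(hillSimpsonEvenness(c(0.5, 0.25, 0.25)), (8 / 3) / 3)
  expect_true(is.na(hillSimpsonEvenness(rep(0, 5))))
  set.seed(4)
  for (i in 1:20) {
    S <- sample(2:12, 1)
    ab <- rexp(S) + 1e-6
    e <- hillSimpsonEvenness(ab)
    expect_gte(e, 1 / S - 1e-12)
    expect_lte(e, 1 + 1e-12)
  }
})

test_that("cell trends recover exact lines and hand-computed slopes", {
  years <- 0:4
  exact <- matrix(2 + 0.5 * years, 1)
  tr <- fitCellTrends(exact, years)
  expect_equal(tr$slope, 0.5)
  expect_equal(tr$variability, 0)
  flat <- matrix(3, 1, 5)
  trF <- fitCellTrends(flat, years)
  expect_equal(trF$slope, 0)
  expect_equal(trF$variability, 0)
  # y = (1, 2, 2) at t = (0, 1, 2): closed-form OLS slope = 0.5
  tr3 <- fitCellTrends(matrix(c(1, 2, 2), 1), 0:2)
  expect_equal(tr3$slope, 0.5)
})

test_that("slope maps equal the closed-form OLS on random surfaces", {
  set.seed(6)
  years <- 1998:2007
  vals <- matrix(rnorm(50 * 10, 10), 50, 10)
  tr <- fitCellTrends(vals, years)
  t0 <- years - mean(years)
  brute <- apply(vals, 1, function(y)
    sum(t0 * (y - mean(y))) / sum(t0^2))
  expect_equal(tr$slope, unname(brute), tolerance = 1e-12)
  # raw-residual option reproduces var of OLS residuals
  trRaw <- fitCellTrends(vals, years, standardize = "none")
  res1 <- vals[1, ] - mean(vals[1, ]) - brute[1] * t0
  expect_equal(trRaw$variability[1], var(res1), tolerance = 1e-12)
})

test_that("identical surfaces give zero deltas and antisymmetric comparisons", {
  study <- simulateStudy(91, nSpecies = 4, nSites = 10, nYears = 6,
                         nGridCells = 48)
  pa <- asPosteriorDraws(study@params, "pa")
  ab <- asPosteriorDraws(study@params, "ab")
  stats <- suppressWarnings(buildDesignMatrix(study@covariates))@stats
  surf <- diversitySurface(pa, ab, study@gridCovariates, stats,
                           scenario = "full")
  cmpSame <- scenarioComparison(surf, surf, surf)
  expect_true(all(abs(cmpSame$deltas[c("dMean", "dSlope",
                                       "dVariability")]) < 1e-12))
  # antisymmetry of deltas in the surface arguments
  scen <- buildScenario(study@gridCovariates, "climate_only")
  surf2 <- diversitySurface(pa, ab, scen, stats,
                            scenario = "climate_only")
  ab1 <- scenarioComparison(surf, surf2, surf2)$deltas
  ab2 <- scenarioComparison(surf2, surf, surf)$deltas
  expect_equal(ab1$dSlope, -ab2$dSlope, tolerance = 1e-12)
  expect_equal(ab1$dMean, -ab2$dMean, tolerance = 1e-12)
})

test_that("diversity surfaces take values in their analytic ranges", {
  study <- simulateStudy(92, nSpecies = 5, nSites = 10, nYears = 6,
                         nGridCells = 48)
  pa <- asPosteriorDraws(study@params, "pa")
  ab <- asPosteriorDraws(study@params, "ab")
  stats <- suppressWarnings(buildDesignMatrix(study@covariates))@stats
  surf <- diversitySurface(pa, ab, study@gridCovariates, stats)
  S <- length(study@params@speciesNames)
  expect_true(all(surf@richness >= 0 & surf@richness <= S))
  expect_true(all(surf@evenness > 0 & surf@evenness <= 1))
  expect_equal(dim(surf@richness),
               c(48, length(unique(study@gridCovariates$year))))
})
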
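# Generating parameters, community simulation and the ground-truth
# variance partition.

traits6 <- generateTraits(21, 6)

test_that("zero species-deviation scale collapses B onto the trait regression", {
  p <- generateParameters(1, traits6, omegaScale = 0)
  Tm <- encodeTraits(traits6)
  expect_equal(p@pa$B, p@pa$Gamma %*% t(Tm),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(p@ab$B, p@ab$Gamma %*% t(Tm),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("zero factor counts remove all random-effect structure", {
  p <- generateParameters(2, traits6,
                          nFactorsPerLevel = c(site = 0L, year = 0L,
                                               zone = 0L))
  expect_true(all(vapply(p@pa$Lambda, nrow, integer(1)) == 0))
  set.seed(5)
  X <- cbind(1, matrix(rnorm(40 * 18), 40), log(150))
  colnames(X) <- p@covNames
  d <- new("DesignMatrix", X = X, blocks = p@blocks, stats = list(),
           units = data.frame(site = paste0("s", 1:40), year = 2000,
                              zone = "zone1", effort_days = 150))
  # same seed, same design: community is a pure function of (params, seed)
  c1 <- simulateCommunity(p, d, seed = 9)
  c2 <- simulateCommunity(p, d, seed = 9)
  expect_identical(SummarizedExperiment::assay(c1, "counts"),
                   SummarizedExperiment::assay(c2, "counts"))
})

test_that("a silenced climate block has zero true climate share", {
  p <- generateParameters(3, traits6,
                          effectScales = list(intercept = 0.6,
                                              habitat = 0.35, climate = 0,
                                              effort = 0.08))
  set.seed(7)
  X <- cbind(1, matrix(rnorm(200 * 18), 200), log(150))
  colnames(X) <- p@covNames
  d <- new("DesignMatrix", X = X, blocks = p@blocks, stats = list(),
           units = data.frame(row = 1:200))
  vp <- trueVariancePartition(p, d, part = "pa")
  expect_equal(unname(vp@shares[1, "climate", ]), rep(0, 6))
  expect_equal(apply(vp@shares[1, , ], 2, sum), rep(1, 6),
               ignore_attr = TRUE)
})

test_that("true shares always sum to one and a single source takes share 1", {
  p <- generateParameters(4, traits6,
                          nFactorsPerLevel = c(site = 0L, year = 0L,
                                               zone = 0L),
                          effectScales = list(intercept = 0.6,
                                              habitat = 0.4, climate = 0,
                                              effort = 0.05))
  set.seed(8)
  X <- cbind(1, matrix(rnorm(150 * 18), 150), log(120))
  colnames(X) <- p@covNames
  d <- new("DesignMatrix", X = X, blocks = p@blocks, stats = list(),
           units = data.frame(row = 1:150))
  vp <- trueVariancePartition(p, d, part = "ab")
  expect_equal(unname(vp@shares[1, "habitat", ]), rep(1, 6),
               tolerance = 1e-10)
})

test_that("simulated prevalence matches the probit calibration", {
  # B = 0, no random effects: every species occurs with probability 1/2
  p <- generateParameters(5, traits6,
                          nFactorsPerLevel = c(site = 0L, year = 0L,
                                               zone = 0L),
                          effectScales = list(intercept = 0, habitat = 0,
                                              climate = 0, effort = 0))
  p@pa$B[] <- 0  # remove the intercept/effort location offsets too
  n <- 2000
  set.seed(10)
  X <- cbind(1, matrix(rnorm(n * 18), n), log(150))
  colnames(X) <- p@covNames
  d <- new("DesignMatrix", X = X, blocks = p@blocks, stats = list(),
           units = data.frame(site = paste0("s", seq_len(n)), year = 2000,
                              zone = "zone1", effort_days = 150))
  comm <- simulateCommunity(p, d, seed = 11)
  prev <- rowMeans(presenceAbsence(comm))
  se <- sqrt(0.25 / n)
  expect_true(all(abs(prev - 0.5) < 3 * se))
})

test_that("prevalence calibration holds across replicate simulations", {
  # known intercepts, no other effects: prevalence ~ Phi(intercept)
  intercepts <- c(-1, -0.3, 0.4)
  tr <- generateTraits(31, 3)
  p <- generateParameters(6, tr,
                          nFactorsPerLevel = c(site = 0L, year = 0L,
                                               zone = 0L),
                          effectScales = list(intercept = 0, habitat = 0,
                                              climate = 0, effort = 0))
  p@pa$B[] <- 0
  p@pa$B[1, ] <- intercepts
  n <- 400
  X <- cbind(1, matrix(0, n, 18), log(150))
  colnames(X) <- p@covNames
  d <- new("DesignMatrix", X = X, blocks = p@blocks, stats = list(),
           units = data.frame(site = paste0("s", seq_len(n)), year = 2000,
                              zone = "zone1", effort_days = 150))
  prev <- sapply(1:20, function(s)
    rowMeans(presenceAbsence(simulateCommunity(p, d, seed = 100 + s))))
  target <- pnorm(intercepts)
  se <- sqrt(target * (1 - target) / (20 * n))
  expect_true(all(abs(rowMeans(prev) - target) < 3 * se))
})

test_that("a saturating predictor makes every unit occupied", {
  tr <- generateTraits(41, 2)
  p <- generateParameters(7, tr,
                          nFactorsPerLevel = c(site = 0L, year = 0L,
                                               zone = 0L),
                          effectScales = list(intercept = 0, habitat = 0,
                                              climate = 0, effort = 0))
  p@pa$B[] <- 0
  p@pa$B[1, ] <- 8  # Phi(8) ~ 1
  n <- 300
  X <- cbind(1, matrix(0, n, 18), log(150))
  colnames(X) <- p@covNames
  d <- new("DesignMatrix", X = X, blocks = p@blocks, stats = list(),
           units = data.frame(site = paste0("s", seq_len(n)), year = 2000,
                              zone = "zone1", effort_days = 150))
  comm <- simulateCommunity(p, d, seed = 12)
  expect_true(all(presenceAbsence(comm)))
  # presence implies a count of at least 1
  expect_true(all(SummarizedExperiment::assay(comm, "counts") >= 1))
})

test_that("the full study generator yields a well-specified, reproducible study", {
  s1 <- simulateStudy(77, nSpecies = 5, nSites = 12, nYears = 6,
                      nGridCells = 48)
  s2 <- simulateStudy(77, nSpecies = 5, nSites = 12, nYears = 6,
                      nGridCells = 48)
  expect_identical(SummarizedExperiment::assay(s1@community, "counts"),
                   SummarizedExperiment::assay(s2@community, "counts"))
  expect_identical(s1@gridCovariates, s2@gridCovariates)
  # sampled sites are a subset of grid cells, southern-weighted
  cd <- SummarizedExperiment::colData(s1@community)
  expect_true(all(cd$cell %in% s1@gridCovariates$cell))
  expect_true(all(cd$effort_days >= 1))
  band <- as.integer(sub("zone", "", cd$zone))
  expect_gt(sum(band <= 2), sum(band >= 3))  # bias towards the south
  # all covariates finite, every positive count has a finite log
  expect_true(all(is.finite(as.matrix(
    s1@covariates[setdiff(covariateColumns(), "hab_clumpiness")]))))
  cnt <- SummarizedExperiment::assay(s1@community, "counts")
  expect_true(all(is.finite(log(cnt[cnt > 0]))))
})
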
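# Sampler correctness: conjugate closed form, maximum-likelihood probit
# oracle, abundance-part behaviour, masking and prior structure.

test_that("Gaussian debug mode matches the closed-form conjugate posterior", {
  set.seed(42)
  n <- 500; K <- 5
  X <- cbind(1, matrix(rnorm(n * (K - 1)), n))
  colnames(X) <- c("intercept", paste0("x", 1:4))
  beta <- c(0.5, 1, -1, 0.3, 0)
  y <- matrix(X %*% beta + rnorm(n), n, 1)
  spec <- hurdleModelSpec(nFactors = c(site = 0, year = 0, zone = 0),
                          fixedGamma = matrix(0, K, 1),
                          fixedOmega = diag(1, K),
                          gaussianDebug = TRUE, chains = 2,
                          iterations = 1000, seed = 3)
  fit <- fitPA(y, rawDesign(X), spec = spec)
  # with everything else fixed, retained B draws are iid from the exact
  # posterior, so the Monte-Carlo SE of the mean is sd / sqrt(ndraws)
  closed <- solve(crossprod(X) + diag(1, K), crossprod(X, y))
  est <- posteriorMean(fit, "B")
  mcse <- apply(fit@B[, , 1], 2, sd) / sqrt(nDraws(fit))
  expect_true(all(abs(est - closed) < 3 * mcse))
})

test_that("probit fits agree with the maximum-likelihood oracle", {
  set.seed(11)
  n <- 2000
  X <- cbind(1, matrix(rnorm(n * 2), n))
  colnames(X) <- c("intercept", "x1", "x2")
  beta <- c(0.2, 0.8, -0.5)
  y <- matrix((X %*% beta + rnorm(n) > 0) * 1, n, 1)
  spec <- hurdleModelSpec(nFactors = c(site = 0, year = 0, zone = 0),
                          chains = 2, iterations = 1200, seed = 5)
  fit <- fitPA(y, rawDesign(X), spec = spec)
  ml <- coef(glm(y ~ X - 1, family = binomial(link = "probit")))
  expect_true(all(abs(posteriorMean(fit, "B") - ml) < 0.15))
})

test_that("an all-absent species gets a negative intercept posterior", {
  set.seed(2)
  n <- 300
  X <- cbind(intercept = rep(1, n))
  y <- matrix(0, n, 1)
  spec <- hurdleModelSpec(nFactors = c(site = 0, year = 0, zone = 0),
                          chains = 1, iterations = 400, seed = 1)
  fit <- fitPA(y, rawDesign(X), spec = spec)
  expect_lt(posteriorMean(fit, "B")[1], 0)  # prior mean is 0
})

test_that("abundance residual SD is recovered from positive units", {
  set.seed(6)
  n <- 1000
  X <- cbind(intercept = rep(1, n))
  counts <- matrix(round(exp(2 + rnorm(n, 0, 0.5))), n, 1)
  counts[counts < 1] <- 1
  spec <- hurdleModelSpec(nFactors = c(site = 0, year = 0, zone = 0),
                          chains = 2, iterations = 1000, seed = 4)
  fit <- fitAB(counts, rawDesign(X), spec = spec)
  expect_lt(abs(mean(fit@sigma[, 1]) - 0.5), 0.05)
})

test_that("a constant response concentrates the intercept at its log", {
  n <- 200
  X <- cbind(intercept = rep(1, n))
  counts <- matrix(7, n, 1)
  spec <- hurdleModelSpec(nFactors = c(site = 0, year = 0, zone = 0),
                          chains = 1, iterations = 600, seed = 2)
  fit <- fitAB(counts, rawDesign(X), spec = spec)
  expect_lt(abs(posteriorMean(fit, "B")[1] - log(7)), 0.02)
})

test_that("absent units contribute nothing to the abundance likelihood", {
  set.seed(9)
  n <- 150
  X <- cbind(1, x = rnorm(n)); colnames(X) <- c("intercept", "x")
  counts <- matrix(rpois(n, 20) + 1, n, 1, dimnames = list(NULL, "u"))
  absent <- runif(n) < 0.4
  counts[absent, 1] <- 0
  spec <- hurdleModelSpec(nFactors = c(site = 0, year = 0, zone = 0),
                          chains = 1, iterations = 300, seed = 7)
  # the full table with absences and the table restricted to the present
  # units carry the same likelihood, hence identical draw streams
  f1 <- fitAB(counts, rawDesign(X), spec = spec)
  pos <- !absent
  f2 <- fitAB(counts[pos, , drop = FALSE],
              rawDesign(X[pos, , drop = FALSE]), spec = spec)
  expect_equal(f1@B, f2@B, tolerance = 1e-12)
  expect_equal(f1@sigma, f2@sigma, tolerance = 1e-12)
})

test_that("an informative trait prior shrinks a rare species' coefficients", {
  set.seed(15)
  n <- 250; S <- 16
  X <- cbind(1, x1 = rnorm(n), x2 = rnorm(n))
  colnames(X) <- c("intercept", "x1", "x2")
  traits <- data.frame(species = sprintf("sp%02d", 1:S),
                       wing_span = seq(18, 50, length.out = S),
                       host_group = rep(hostGroups(), length.out = S))
  # strong trait-driven coefficients with tiny species deviations; the
  # largest-winged species is made rare by its own trait signal
  Tm <- encodeTraits(traits)
  Gamma <- matrix(0, 3, ncol(Tm))
  Gamma[1, 1] <- -0.8; Gamma[1, 2] <- -1.0
  Gamma[2, 1] <- 0.8; Gamma[3, 2] <- -0.8
  B <- Gamma %*% t(Tm) + matrix(rnorm(3 * S, 0, 0.08), 3, S)
  y <- (X %*% B + matrix(rnorm(n * S), n, S) > 0) * 1
  colnames(y) <- traits$species
  spec <- hurdleModelSpec(nFactors = c(site = 0, year = 0, zone = 0),
                          chains = 1, iterations = 800, seed = 8)
  withTr <- fitPA(y, rawDesign(X), traits = traits, spec = spec)
  noTr <- fitPA(y, rawDesign(X), traits = NULL, spec = spec)
  rare <- which.min(colSums(y))
  sdWith <- apply(withTr@B[, , rare], 2, sd)
  sdNo <- apply(noTr@B[, , rare], 2, sd)
  expect_lt(mean(sdWith), mean(sdNo))
})

test_that("species are exchangeable up to Monte-Carlo error", {
  set.seed(20)
  n <- 300; S <- 3; K <- 3
  X <- cbind(1, matrix(rnorm(n * 2), n))
  colnames(X) <- c("intercept", "x1", "x2")
  y <- matrix(X %*% matrix(c(0, 1, -0.5, 0.5, 0, 0.5, -0.5, 0.5, 0), K, S) +
                rnorm(n * S), n, S)
  colnames(y) <- c("a", "b", "c")
  spec <- hurdleModelSpec(nFactors = c(site = 0, year = 0, zone = 0),
                          fixedGamma = matrix(0, K, 1),
                          fixedOmega = diag(1, K),
                          gaussianDebug = TRUE, chains = 1,
                          iterations = 1500, seed = 6)
  f1 <- fitPA(y, rawDesign(X), spec = spec)
  perm <- c(3, 1, 2)
  f2 <- fitPA(y[, perm], rawDesign(X), spec = spec)
  m1 <- posteriorMean(f1, "B")[, perm]
  m2 <- posteriorMean(f2, "B")
  expect_equal(m1, m2, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("draw bookkeeping and diagnostics are consistent", {
  set.seed(30)
  n <- 120
  X <- cbind(1, x = rnorm(n)); colnames(X) <- c("intercept", "x")
  y <- matrix((rnorm(n) > 0) * 1, n, 1)
  spec <- hurdleModelSpec(nFactors = c(site = 0, year = 0, zone = 0),
                          chains = 2, iterations = 200, burnin = 0.5,
                          thin = 2, seed = 9)
  fit <- fitPA(y, rawDesign(X), spec = spec)
  expect_equal(nDraws(fit), 2 * (200 - 100) / 2)
  expect_true(all(is.finite(fit@diagnostics$rhat)))
})
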
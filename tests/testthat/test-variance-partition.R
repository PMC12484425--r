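# Predictive and conditional variance partitioning: additivity oracles,
# law of total variance, clustering, trait pooling and the
# dominant-driver summary.

# draws with random coefficients over the canonical toy layout:
# intercept | habitat = 2 columns | climate = 2 columns
toyDraws <- function(nd = 8, S = 5, seed = 1, Lambda = list(),
                     part = "PA") {
  set.seed(seed)
  covs <- c("intercept", "h1", "h2", "c1", "c2")
  blocks <- list(intercept = 1L, habitat = 2:3, climate = 4:5)
  B <- array(rnorm(nd * 5 * S), c(nd, 5, S))
  d <- manualDraws(matrix(0, 5, S, dimnames = list(covs, NULL)),
                   part = part, blocks = blocks, nDraw = nd,
                   Lambda = Lambda,
                   Eta = lapply(Lambda, function(L)
                     array(0, c(nd, 1, dim(L)[2]))))
  d@B <- B
  d
}

toyGrid <- function(n = 200, seed = 2, correlated = FALSE) {
  set.seed(seed)
  X <- cbind(intercept = 1, h1 = rnorm(n), h2 = rnorm(n),
             c1 = rnorm(n), c2 = rnorm(n))
  if (correlated) {
    X[, "c1"] <- 0.9 * X[, "h1"] + 0.3 * rnorm(n)
    X[, "c2"] <- -0.8 * X[, "h2"] + 0.4 * rnorm(n)
  }
  rawDesign(X, blocks = list(intercept = 1L, habitat = 2:3,
                             climate = 4:5))
}

test_that("group variances add up exactly to the empirical predictor variance", {
  d <- toyDraws()
  g <- toyGrid()
  vp <- variancePartition(d, g)
  Xs <- g@X[, 2:5]
  for (k in seq_len(nDraws(d))) {
    B <- d@B[k, 2:5, ]
    F <- Xs %*% B
    empVar <- colMeans(F^2) - colMeans(F)^2  # population variance oracle
    got <- vp@variances[k, "habitat", ] + vp@variances[k, "climate", ]
    expect_equal(unname(got), unname(empVar), tolerance = 1e-10)
  }
  expect_equal(apply(vp@shares, c(1, 3), sum),
               matrix(1, nDraws(d), 5), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("orthogonal one-column groups split in proportion to beta^2 var(x)", {
  n <- 200
  # exactly orthogonal, mean-zero columns so cross-covariances vanish
  X <- cbind(intercept = 1, h1 = 2 * rep(c(1, -1), n / 2),
             c1 = 0.5 * rep(c(1, 1, -1, -1), n / 4))
  g <- rawDesign(X, blocks = list(intercept = 1L, habitat = 2L,
                                  climate = 3L))
  B <- matrix(c(0, 0.5, 1.5), 3, 1,
              dimnames = list(colnames(X), "sp"))
  vp <- variancePartition(manualDraws(B, blocks = g@blocks), g)
  fHab <- X[, "h1"] * 0.5; fCli <- X[, "c1"] * 1.5
  pv <- function(x) mean(x^2) - mean(x)^2
  expect_equal(vp@variances[1, "habitat", 1], pv(fHab), tolerance = 1e-10)
  expect_equal(vp@variances[1, "climate", 1], pv(fCli), tolerance = 1e-10)
})

test_that("correlated blocks keep exact additivity with flagged negatives", {
  d <- toyDraws(nd = 6, seed = 3)
  g <- toyGrid(correlated = TRUE, seed = 5)
  vp <- variancePartition(d, g)
  Xs <- g@X[, 2:5]
  for (k in seq_len(6)) {
    F <- Xs %*% d@B[k, 2:5, ]
    empVar <- colMeans(F^2) - colMeans(F)^2
    expect_equal(unname(vp@variances[k, "habitat", ] +
                          vp@variances[k, "climate", ]),
                 unname(empVar), tolerance = 1e-10)
  }
  # under strong cross-block correlation some components go negative,
  # and they are flagged rather than truncated
  expect_true(any(vp@variances[, c("habitat", "climate"), ] < 0))
  expect_true(any(vp@negativeFlag))
})

test_that("silent climate coefficients put no share on climate", {
  d <- toyDraws(nd = 5, seed = 6,
                Lambda = list(site = array(0.5, c(5, 1, 5))))
  d@B[, 4:5, ] <- 0
  vp <- variancePartition(d, toyGrid())
  expect_equal(max(abs(vp@shares[, "climate", ])), 0)
  sums <- apply(vp@shares[, c("habitat", "site"), ], c(1, 3), sum)
  expect_equal(sums, matrix(1, 5, 5), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("shares are invariant to translating design columns", {
  d <- toyDraws(nd = 4, seed = 8)
  g <- toyGrid(seed = 9)
  vp1 <- variancePartition(d, g)
  g2 <- g
  g2@X[, "h1"] <- g2@X[, "h1"] + 5
  g2@X[, "c2"] <- g2@X[, "c2"] - 3
  vp2 <- variancePartition(d, g2)
  expect_equal(vp1@shares, vp2@shares, tolerance = 1e-10)
})

test_that("groups must partition the candidate columns", {
  d <- toyDraws()
  g <- toyGrid()
  expect_error(variancePartition(d, g, groups = list(habitat = 2:3)),
               "partition")
  expect_error(variancePartition(d, g,
                                 groups = list(habitat = 2:4,
                                               climate = 4:5)),
               "partition")
})

test_that("k-means profiles recover well-separated compositions", {
  skip_if_not_installed("mclust")
  set.seed(10)
  centers <- rbind(c(0.8, 0.1, 0.05, 0.05),
                   c(0.1, 0.8, 0.05, 0.05),
                   c(0.05, 0.1, 0.25, 0.6))
  colnames(centers) <- c("forest", "water", "wetland", "agriculture")
  truth <- sample(1:3, 120, replace = TRUE)
  comp <- centers[truth, ] + matrix(rnorm(480, 0, 0.015), 120, 4)
  km <- kmeansProfiles(comp, k = 3, seed = 4)
  expect_equal(mclust::adjustedRandIndex(km$cluster, truth), 1)
  # dominant categories name the profiles
  expect_setequal(unique(km$labels), c("forest", "water", "agriculture"))
  # determinism
  km2 <- kmeansProfiles(comp, k = 3, seed = 4)
  expect_identical(km$labels, km2$labels)
})

test_that("degenerate clustering inputs are rejected", {
  comp <- matrix(0.25, 10, 4)
  expect_error(kmeansProfiles(comp, k = 3), "distinct")
  expect_error(kmeansProfiles(matrix(runif(8), 2, 4), k = 3), "more clusters")
})

test_that("conditional partitions obey the law of total variance", {
  d <- toyDraws(nd = 10, seed = 11,
                Lambda = list(site = array(0.3, c(10, 2, 5))))
  g <- toyGrid(n = 240, seed = 12)
  set.seed(13)
  ctx <- sample(c("a", "b", "c"), 240, replace = TRUE)
  cp <- conditionalVPEnvironmental(d, g, ctx)
  expect_equal(cp@within + cp@between, cp@total, tolerance = 1e-8)
  # random-effect variance is constant across cells and sits within
  expect_equal(unname(cp@reVariance[1, ]), rep(2 * 0.3^2, 5))

  # a single context collapses between to zero
  cp1 <- conditionalVPEnvironmental(d, g, rep("all", 240))
  expect_equal(max(abs(cp1@between)), 0)
  expect_equal(cp1@within, cp1@total, tolerance = 1e-12)
})

test_that("contexts with identical covariate distributions have small between-share", {
  d <- toyDraws(nd = 4, seed = 14)
  fr <- replicate(10, {
    g <- toyGrid(n = 400, seed = sample.int(1e6, 1))
    ctx <- rep(c("x", "y"), 200)  # same generator, arbitrary labels
    cp <- conditionalVPEnvironmental(d, g, ctx)
    mean(cp@between / cp@total)
  })
  expect_lt(mean(fr), 0.05)
})

test_that("merging contexts never increases the between-share", {
  d <- toyDraws(nd = 6, seed = 15)
  g <- toyGrid(n = 300, seed = 16)
  ctx4 <- rep(c("a", "b", "c", "d"), 75)
  merged <- ifelse(ctx4 %in% c("a", "b"), "ab", ctx4)
  cp4 <- conditionalVPEnvironmental(d, g, ctx4)
  cpM <- conditionalVPEnvironmental(d, g, merged)
  expect_true(all(cpM@between <= cp4@between + 1e-12))
})

test_that("small contexts are excluded from per-context partitions with warning", {
  d <- toyDraws(nd = 3, seed = 17)
  g <- toyGrid(n = 101, seed = 18)
  ctx <- c(rep("big", 100), "lonely")
  expect_warning(cp <- conditionalVPEnvironmental(d, g, ctx), "lonely")
  expect_named(cp@results, "big")
  expect_equal(cp@within + cp@between, cp@total, tolerance = 1e-8)
})

test_that("trait-group pooling preserves single-species draws and share sums", {
  d <- toyDraws(nd = 20, seed = 19,
                Lambda = list(site = array(0.4, c(20, 1, 5))))
  vp <- variancePartition(d, toyGrid())
  spp <- dimnames(vp@shares)[[3]]
  groups <- setNames(c("solo", "pair", "pair", "rest", "rest"), spp)
  fun <- conditionalVPFunctional(vp, groups)
  expect_equal(unname(fun$solo$draws[, "habitat"]),
               unname(vp@shares[, "habitat", 1]))
  expect_equal(nrow(fun$pair$draws), 2 * 20)
  # habitat + climate + RE shares still total one for pooled members
  reShare <- as.vector(vp@shares[, "site", groups == "pair"])
  expect_equal(unname(rowSums(fun$pair$draws)) + reShare,
               rep(1, 40), tolerance = 1e-10)
  expect_no_warning(conditionalVPFunctional(vp, groups[0]))
})

test_that("two species with identically distributed draws pool indistinguishably", {
  set.seed(20)
  nd <- 400
  d <- toyDraws(nd = nd, seed = 20)
  # species 1 and 2 get iid coefficient draws from the same law
  d@B[, , 2] <- array(rnorm(nd * 5), c(nd, 5))
  d@B[, , 1] <- array(rnorm(nd * 5), c(nd, 5))
  vp <- variancePartition(d, toyGrid())
  groups <- setNames(c("g", "g", "h", "h", "h"),
                     dimnames(vp@shares)[[3]])
  fun <- conditionalVPFunctional(vp, groups)
  ks <- suppressWarnings(
    ks.test(fun$g$draws[, "habitat"], vp@shares[, "habitat", 1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("dominant-driver counts bound and degenerate cases behave", {
  d <- toyDraws(nd = 30, seed = 21)
  vp <- variancePartition(d, toyGrid())
  ddc <- dominantDriverCounts(vp)
  expect_true(all(ddc$counts <= 5 & ddc$counts >= 0))
  # climate silenced: habitat dominates for every species in every draw
  d0 <- d; d0@B[, 4:5, ] <- 0
  vp0 <- variancePartition(d0, toyGrid())
  expect_true(all(dominantDriverCounts(vp0)$counts == 5))
  # swapping the habitat and climate blocks of both coefficients and
  # grid columns mirrors the decomposition exactly: counts flip to S - n
  dS <- d
  dS@B[, 2:3, ] <- d@B[, 4:5, ]
  dS@B[, 4:5, ] <- d@B[, 2:3, ]
  g <- toyGrid(seed = 22)
  gS <- g
  gS@X[, 2:3] <- g@X[, 4:5]
  gS@X[, 4:5] <- g@X[, 2:3]
  cA <- dominantDriverCounts(variancePartition(d, g))$counts
  cB <- dominantDriverCounts(variancePartition(dS, gS))$counts
  expect_equal(cA + cB, rep(5, 30), ignore_attr = TRUE)
})
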
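# Shared fixtures and independent oracles for the test suite. All
# fixtures are generated in code; the expensive reference fit (the
# desk-scale recovery study) is computed once per session and memoised.

.fixtureCache <- new.env(parent = emptyenv())

# Desk-scale reference study and hurdle fit: 15 species, 80 sites,
# 12 years, 500-cell grid, 2 x 2000 iterations.
cachedRecoveryFit <- function() {
  if (!is.null(.fixtureCache$recovery)) return(.fixtureCache$recovery)
  study <- simulateStudy(1, nSpecies = 15, nSites = 80, nYears = 12,
                         nGridCells = 500)
  community <- prevalenceFilter(study@community, 0.10)
  traits <- study@traits[study@traits$species %in% rownames(community), ]
  design <- suppressWarnings(buildDesignMatrix(study@covariates))
  spec <- hurdleModelSpec(seed = 2)
  pa <- fitPA(community, design, traits, spec)
  ab <- fitAB(community, design, traits, spec)
  gridDesign <- buildDesignMatrix(study@gridCovariates,
                                  stats = design@stats)
  .fixtureCache$recovery <- list(study = study, community = community,
                                 traits = traits, design = design,
                                 gridDesign = gridDesign, pa = pa, ab = ab)
  .fixtureCache$recovery
}

# Plain DesignMatrix wrapper around a raw matrix for sampler-level tests.
rawDesign <- function(X, blocks = NULL) {
  if (is.null(blocks)) {
    blocks <- list(intercept = 1L)
    if (ncol(X) > 1) blocks$habitat <- 2:ncol(X)
  }
  new("DesignMatrix", X = X, blocks = blocks, stats = list(),
      units = data.frame(row = seq_len(nrow(X))))
}

# Brute-force clumpiness by explicit adjacency enumeration (the oracle
# kept deliberately loop-based and independent of the implementation).
bruteClumpiness <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  like <- 0; total <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      total <- total + 1
      if (mask[ii, jj]) like <- like + 1
    }
  }
  P <- mean(mask)
  if (P == 0 || P == 1 || total == 0) return(NA_real_)
  G <- like / total
  if (G < P && P < 0.5) (G - P) / P else (G - P) / (1 - P)
}

bruteEntropy <- function(codes, base = 2) {
  p <- as.vector(table(codes)) / length(codes)
  -sum(p * log(p, base = base))
}

# Single-draw PosteriorDraws with hand-set coefficients, for prediction
# and variance-partition tests that need exact ground truth.
manualDraws <- function(B, part = "PA", sigma = NULL, Lambda = list(),
                        Eta = list(), blocks = NULL, nDraw = 1) {
  K <- nrow(B); S <- ncol(B)
  if (is.null(blocks)) {
    blocks <- list(intercept = 1L)
    if (K > 1) blocks$habitat <- 2:K
  }
  Barr <- array(rep(B, each = nDraw), c(nDraw, K, S))
  new("PosteriorDraws", part = part, B = Barr,
      Gamma = array(0, c(nDraw, K, 1)), Omega = array(diag(K), c(nDraw, K, K)),
      Lambda = Lambda, Eta = Eta,
      sigma = if (part == "AB") {
        if (is.null(sigma)) sigma <- rep(1e-8, S)
        matrix(rep(sigma, each = nDraw), nDraw, S)
      } else matrix(numeric(0), nDraw, 0),
      covNames = if (!is.null(rownames(B))) rownames(B) else
        paste0("c", seq_len(K)),
      speciesNames = if (!is.null(colnames(B))) colnames(B) else
        paste0("sp", seq_len(S)),
      blocks = blocks,
      levelIds = lapply(Lambda, function(x) "<none>"),
      nChains = 1L, diagnostics = list())
}

# Covariate table with habitat-driven temporal trends and purely
# interannual climate noise, for the scenario-attribution checks.
trendNoiseCovariates <- function(seed, nCells = 40, nYears = 8) {
  set.seed(seed)
  years <- seq(1998, length.out = nYears)
  base <- data.frame(cell = seq_len(nCells),
                     lat = seq(60, 70, length.out = nCells))
  conif0 <- runif(nCells, 0.3, 0.6)
  trendRate <- runif(nCells, -0.035, 0.035)  # habitat change per year
  out <- do.call(rbind, lapply(seq_along(years), function(ti) {
    t <- ti - 1
    conif <- pmin(0.9, pmax(0.05, conif0 + trendRate * t))
    semin <- pmax(0.02, 0.35 - conif / 2)
    data.frame(cell = base$cell, year = years[ti], lat = base$lat,
               hab_broadleaf = 0.08 + 0.1 * (1 - conif),
               hab_conifer = conif,
               hab_mixed = 0.1 + 0.05 * sin(base$lat),
               hab_seminatural = semin,
               hab_clumpiness = 0.4 + 0.3 * (conif - 0.5),
               hab_entropy = 1.6 - 0.5 * (conif - 0.5),
               clim_gdd = 1100 - 40 * (base$lat - 60) + rnorm(nCells, 0, 30),
               clim_cdd = 1500 + 50 * (base$lat - 60) + rnorm(nCells, 0, 40),
               clim_snow = 25 + 2 * (base$lat - 60) + rnorm(nCells, 0, 2.5),
               clim_precip = 350 + rnorm(nCells, 0, 12),
               effort_days = 150)
  }))
  rownames(out) <- NULL
  out
}
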
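## Species traits, generating parameters, community simulation and the
## full synthetic study emulating a national light-trap monitoring design.

# Canonical 20-column design layout (matches buildDesignMatrix()).
.defaultCovLayout <- function() {
  nm <- c("intercept",
          as.vector(rbind(.habLinear, paste0(.habLinear, "_sq"))),
          .habConfig,
          as.vector(rbind(.climLinear, paste0(.climLinear, "_sq"))),
          "effort_logdays")
  list(covNames = nm,
       blocks = list(intercept = 1L, habitat = 2:11, climate = 12:19,
                     effort = 20L))
}

#' Generate a species trait table
#'
#' Wing spans are lognormal around 30 mm with a small fraction of wingless
#' (span 0) species, mirroring the composition of a boreal macro-moth
#' assemblage; host-plant groups are drawn with deciduous/herbaceous
#' feeders most frequent.
#'
#' @param seed integer seed.
#' @param nSpecies number of species.
#' @param winglessProb probability of a wingless-female species.
#' @return data.frame `species`, `wing_span`, `host_group`, `wing_bin`.
#' @export
generateTraits <- function(seed, nSpecies, winglessProb = 0.05) {
  set.seed(as.integer(seed))
  w <- exp(rnorm(nSpecies, log(30), 0.22))
  w <- pmin(pmax(w, 18), 58)
  w[runif(nSpecies) < winglessProb] <- 0
  hg <- sample(hostGroups(), nSpecies, replace = TRUE,
               prob = c(0.30, 0.12, 0.12, 0.25, 0.12, 0.09))
  assignWingBins(data.frame(species = sprintf("sp%02d", seq_len(nSpecies)),
                            wing_span = round(w, 1), host_group = hg,
                            stringsAsFactors = FALSE))
}

#' Draw generating parameters from the model's own prior family
#'
#' Species coefficients are drawn as `B_j = Gamma t_j + e_j` with
#' `e_j ~ N(0, Omega)` and a diagonal `Omega` scaled per covariate block,
#' so data simulated from these parameters are exactly well-specified for
#' the fitted model. Trait-effect entries are normal around zero except
#' for two location offsets: the model intercept (set so that average
#' occurrence probability and conditional abundance are realistic) and a
#' positive effort effect. Loadings decay geometrically across factors
#' within a level.
#'
#' @param seed integer seed.
#' @param traits trait table (one row per species; see
#'   [generateTraits()]).
#' @param nFactorsPerLevel named factor counts per random level; a level
#'   with 0 factors carries no random-effect structure.
#' @param effectScales named per-block effect scales (SD units of the
#'   latent predictor per standardized covariate); a block scale of 0
#'   silences both the trait means and the species deviations of that
#'   block.
#' @param omegaScale multiplier on the species-deviation SDs; 0 gives
#'   `B_j = Gamma t_j` exactly.
#' @param lambdaScale named per-level loading SD of the first factor
#'   (halving variance per successive factor).
#' @param sigmaRange range of per-species abundance residual SDs.
#' @param covLayout design layout (`covNames`, `blocks`); defaults to the
#'   canonical 20-column layout.
#' @return a [TrueParameters-class].
#' @export
generateParameters <- function(seed, traits,
                               nFactorsPerLevel = c(site = 2L, year = 1L,
                                                    zone = 1L),
                               effectScales = list(intercept = 0.6,
                                                   habitat = 0.35,
                                                   climate = 0.35,
                                                   effort = 0.08),
                               omegaScale = 1,
                               lambdaScale = c(site = 0.5, year = 0.3,
                                               zone = 0.3),
                               sigmaRange = c(0.4, 0.9),
                               covLayout = .defaultCovLayout()) {
  stopifnot(nrow(traits) >= 1, all(nFactorsPerLevel >= 0), omegaScale >= 0)
  set.seed(as.integer(seed))
  Tm <- encodeTraits(traits)
  S <- nrow(Tm); Tt <- ncol(Tm)
  covNames <- covLayout$covNames; blocks <- covLayout$blocks
  K <- length(covNames)
  blockOf <- rep(NA_character_, K)
  for (b in names(blocks)) blockOf[blocks[[b]]] <- b
  sB <- vapply(blockOf, function(b) effectScales[[b]], numeric(1))
  if (any(sB < 0)) stop("effect scales must be >= 0")
  drawPart <- function(interceptLoc, effortLoc) {
    loc <- numeric(K)
    loc[blocks$intercept] <- interceptLoc
    loc[blocks$effort] <- effortLoc
    Gamma <- matrix(rnorm(K * Tt, 0, rep(0.6 * sB, Tt)), K, Tt)
    Gamma[, 1] <- Gamma[, 1] + loc
    omegaSD <- 0.8 * sB * omegaScale
    if (any(omegaSD < 0)) stop("Omega must be positive semi-definite")
    B <- Gamma %*% t(Tm) + matrix(rnorm(K * S, 0, rep(omegaSD, S)), K, S)
    Lambda <- lapply(names(nFactorsPerLevel), function(r) {
      H <- nFactorsPerLevel[[r]]
      m <- matrix(rnorm(H * S, 0,
                        rep(lambdaScale[[r]] * 2^(-(seq_len(H) - 1) / 2),
                            S)), H, S)
      dimnames(m) <- list(NULL, rownames(Tm))
      m
    })
    names(Lambda) <- names(nFactorsPerLevel)
    dimnames(B) <- list(covNames, rownames(Tm))
    list(B = B, Gamma = Gamma, Lambda = Lambda,
         Omega = diag(omegaSD^2, K), effectScales = effectScales)
  }
  pa <- drawPart(interceptLoc = -1.8, effortLoc = 0.30)
  ab <- drawPart(interceptLoc = 1.6, effortLoc = 0.30)
  sigma <- runif(S, sigmaRange[1], sigmaRange[2])
  new("TrueParameters", pa = pa, ab = ab, sigma = sigma,
      covNames = covNames, blocks = blocks,
      speciesNames = rownames(Tm), traitNames = colnames(Tm))
}

#' Simulate a community from true parameters
#'
#' For each unit and species, the occurrence latent is
#' `z = x B_PA + RE_PA + eps`, `eps ~ N(0, 1)`, with presence iff
#' `z > 0`; where present, the count is
#' `max(1, round(exp(N(x B_AB + RE_AB, sigma_j))))` (counts are floored at
#' 1 because the abundance part conditions on presence). Factor scores are
#' drawn fresh per random level and per part.
#'
#' @param params a [TrueParameters-class].
#' @param design a [DesignMatrix-class] whose columns match
#'   `params@covNames` (the effort column is the log trap-days of each
#'   unit).
#' @param seed integer seed.
#' @param units data.frame per design row with `site`, `year`, `zone`,
#'   `effort_days` and optionally `lat`, `lon`, `cell`; defaults to
#'   `design@units`.
#' @return a [CommunityTable-class].
#' @export
simulateCommunity <- function(params, design, seed, units = design@units) {
  stopifnot(is(params, "TrueParameters"),
            identical(colnames(design@X), params@covNames))
  set.seed(as.integer(seed))
  X <- design@X
  n <- nrow(X); S <- length(params@speciesNames)
  reDraw <- function(Lambda) {
    RE <- matrix(0, n, S)
    for (r in names(Lambda)) {
      H <- nrow(Lambda[[r]])
      if (H == 0) next
      f <- factor(units[[r]])
      eta <- matrix(rnorm(nlevels(f) * H), nlevels(f), H)
      RE <- RE + eta[as.integer(f), , drop = FALSE] %*% Lambda[[r]]
    }
    RE
  }
  zPA <- X %*% params@pa$B + reDraw(params@pa$Lambda) +
    matrix(rnorm(n * S), n, S)
  present <- zPA > 0
  muAB <- X %*% params@ab$B + reDraw(params@ab$Lambda)
  logAb <- muAB + matrix(rnorm(n * S, 0, rep(params@sigma, each = n)), n, S)
  counts <- ifelse(present, pmax(1, round(exp(logAb))), 0)
  dimnames(counts) <- list(NULL, params@speciesNames)
  CommunityTable(t(counts), units)
}

#' Latitude band zones
#'
#' Four equal-width latitude bands standing in for the boreal bioclimatic
#' zones, labelled `zone1` (southernmost) to `zone4`.
#'
#' @param lat numeric latitudes.
#' @param latRange range to divide; defaults to the range of `lat`.
#' @return character zone labels.
#' @export
latitudeZones <- function(lat, latRange = range(lat)) {
  br <- seq(latRange[1], latRange[2], length.out = 5)
  br[1] <- -Inf; br[5] <- Inf
  paste0("zone", findInterval(lat, br, rightmost.closed = TRUE))
}

#' Simulate a complete synthetic monitoring study
#'
#' Generates (1) a clustered land-cover raster series over the study
#' extent, one epoch per land-cover mapping period touched by the study
#' years; (2) daily climate with a latitudinal gradient, interannual
#' noise and a warming trend, summarised to the four climate covariates;
#' (3) a prediction lattice of grid cells (spacing = one 500 m buffer)
#' with habitat and climate covariates per year; (4) a latitude-biased
#' sample of cells hosting traps (the probability of hosting a trap
#' halves per zone band northward, emulating a southern-weighted,
#' non-representative design); (5) trait-structured species parameters
#' and the simulated community at the sampled trap-years.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param nSpecies,nSites,nYears,nGridCells study dimensions (defaults:
#'   15 species, 80 sites, 12 years from 1998, 500 grid cells).
#' @param startYear first study year.
#' @param autocorrScale,changeRate landscape generator settings.
#' @param climateArgs list of overrides passed to [generateClimate()].
#' @param paramArgs list of overrides passed to [generateParameters()].
#' @param gridEffortDays constant effort assigned to prediction-grid
#'   units.
#' @param latRange latitude span of the study extent (degrees north).
#' @return a [SyntheticStudy-class].
#' @export
simulateStudy <- function(seed, nSpecies = 15, nSites = 80, nYears = 12,
                          nGridCells = 500, startYear = 1998L,
                          autocorrScale = 6, changeRate = 0.10,
                          climateArgs = list(), paramArgs = list(),
                          gridEffortDays = 150, latRange = c(60, 70)) {
  seed <- as.integer(seed)
  stopifnot(nSites <= nGridCells)
  years <- seq(startYear, length.out = nYears)
  epochs <- sort(unique(epochForYear(years)))
  gridCols <- max(4L, floor(sqrt(nGridCells / 1.25)))
  gridRows <- ceiling(nGridCells / gridCols)
  buffPx <- 25L  # 500 m buffer at 20 m pixels
  landscape <- generateLandscape(seed + 1L, rows = gridRows * buffPx,
                                 cols = gridCols * buffPx,
                                 nEpochs = length(epochs),
                                 autocorrScale = autocorrScale,
                                 changeRate = changeRate, epochs = epochs)
  cellRow <- rep(seq_len(gridRows), each = gridCols)
  cellCol <- rep(seq_len(gridCols), times = gridRows)
  keep <- seq_len(nGridCells)
  cellRow <- cellRow[keep]; cellCol <- cellCol[keep]
  lat <- latRange[1] + diff(latRange) * (cellRow - 0.5) / gridRows
  cells <- data.frame(cell = seq_len(nGridCells), lat = lat,
                      x = (cellCol - 0.5) * buffPx * 20,
                      y = (cellRow - 0.5) * buffPx * 20)
  cells$zone <- latitudeZones(cells$lat, latRange)

  # habitat features per cell per epoch
  habByEpoch <- lapply(landscape, function(ras) {
    t(vapply(seq_len(nGridCells), function(i) {
      rows <- ((cellRow[i] - 1) * buffPx + 1):(cellRow[i] * buffPx)
      cols <- ((cellCol[i] - 1) * buffPx + 1):(cellCol[i] * buffPx)
      win <- list(rows = rows, cols = cols)
      pr <- bufferProportions(ras, c(mean(cols) * 20, mean(rows) * 20))
      c(hab_broadleaf = unname(pr["broadleaf_forest"]),
        hab_conifer = unname(pr["coniferous_forest"]),
        hab_mixed = unname(pr["mixed_forest"]),
        hab_seminatural = unname(pr["seminatural_herbaceous"]),
        hab_clumpiness = clumpiness(ras, win),
        hab_entropy = marginalEntropy(ras, win),
        setNames(as.numeric(pr), paste0("comp_", names(pr))))
    }, numeric(14)))
  })
  names(habByEpoch) <- as.character(epochs)

  climate <- do.call(generateClimate,
                     c(list(seed = seed + 2L, cells = cells[c("cell", "lat")],
                            years = years), climateArgs))
  clim <- climateFeatures(climate)

  gridCov <- clim
  ep <- as.character(epochForYear(gridCov$year, epochs))
  hab <- do.call(rbind, lapply(seq_len(nrow(gridCov)), function(i)
    habByEpoch[[ep[i]]][gridCov$cell[i], ]))
  gridCov <- cbind(gridCov, hab)
  gridCov$lat <- cells$lat[gridCov$cell]
  gridCov$zone <- cells$zone[gridCov$cell]
  gridCov$effort_days <- gridEffortDays

  # latitude-biased site placement: halving weight per zone band
  set.seed(seed + 3L)
  band <- as.integer(sub("zone", "", cells$zone))
  w <- 2^(-(band - 1))
  siteCells <- sample(cells$cell, nSites, prob = w)
  siteIds <- sprintf("site%03d", seq_len(nSites))
  sampled <- gridCov[gridCov$cell %in% siteCells, ]
  sampled$site <- siteIds[match(sampled$cell, siteCells)]
  sampled$effort_days <- sample(60:198, nrow(sampled), replace = TRUE)
  sampled <- sampled[order(sampled$site, sampled$year), ]
  rownames(sampled) <- NULL

  traits <- generateTraits(seed + 4L, nSpecies)
  params <- do.call(generateParameters,
                    c(list(seed = seed + 5L, traits = traits), paramArgs))
  design <- buildDesignMatrix(sampled)
  community <- simulateCommunity(params, design, seed + 6L,
                                 units = sampled)
  new("SyntheticStudy",
      community = community, covariates = sampled,
      gridCovariates = gridCov, params = params, traits = traits,
      landscape = landscape,
      seeds = list(master = seed, landscape = seed + 1L,
                   climate = seed + 2L, sites = seed + 3L,
                   traits = seed + 4L, params = seed + 5L,
                   community = seed + 6L),
      config = list(nSpecies = nSpecies, nSites = nSites, nYears = nYears,
                    nGridCells = nGridCells, startYear = startYear,
                    autocorrScale = autocorrScale, changeRate = changeRate,
                    gridEffortDays = gridEffortDays, latRange = latRange))
}

#' Wrap true parameters as degenerate posterior draws
#'
#' Builds a single-draw [PosteriorDraws-class] whose coefficient and
#' loading arrays hold the generating parameters exactly. Useful for
#' exercising prediction, variance-partitioning and scenario machinery
#' against analytic ground truth without an MCMC fit. Factor scores are
#' zero, so predictions correspond to the marginal (expected) surface.
#'
#' @param params a [TrueParameters-class].
#' @param part `"pa"` or `"ab"`.
#' @return a [PosteriorDraws-class] with one draw.
#' @export
asPosteriorDraws <- function(params, part = c("pa", "ab")) {
  part <- match.arg(part)
  p <- slot(params, part)
  K <- length(params@covNames); S <- length(params@speciesNames)
  arr <- function(m) array(m, c(1, nrow(m), ncol(m)))
  Lambda <- lapply(p$Lambda, function(L) array(L, c(1, nrow(L), ncol(L))))
  Eta <- lapply(p$Lambda, function(L) array(0, c(1, 1, nrow(L))))
  new("PosteriorDraws",
      part = toupper(part),
      B = arr(p$B), Gamma = arr(p$Gamma),
      Omega = array(p$Omega, c(1, K, K)),
      Lambda = Lambda, Eta = Eta,
      sigma = if (part == "ab") matrix(params@sigma, 1, S) else
        matrix(numeric(0), 1, 0),
      covNames = params@covNames, speciesNames = params@speciesNames,
      blocks = params@blocks,
      levelIds = lapply(p$Lambda, function(L) "<none>"),
      nChains = 1L, diagnostics = list())
}
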
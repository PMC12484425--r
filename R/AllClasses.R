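## Central S4 classes. Data containers are deliberately thin: matrices and
## plain data.frames inside validated S4 shells, with accessors in
## accessors.R. CommunityTable rides on SummarizedExperiment so the usual
## assay/colData machinery applies.

#' Land-cover legend used throughout the package
#'
#' Integer raster codes map positionally onto these category names.
#'
#' @return Character vector of the eight land-cover categories; the code of
#'   category `k` is `k`.
#' @export
#' @examples
#' landCoverLegend()
landCoverLegend <- function() {
  c("broadleaf_forest", "coniferous_forest", "mixed_forest",
    "seminatural_herbaceous", "wetland", "water", "urban", "agriculture")
}

#' Forest category codes
#'
#' The three forest classes merged into the focal mask for the clumpiness
#' metric.
#' @return Integer codes of the forest categories.
#' @export
forestCodes <- function() which(landCoverLegend() %in%
  c("broadleaf_forest", "coniferous_forest", "mixed_forest"))

#' @rdname LandscapeRaster-class
#' @export
setClass("LandscapeRaster",
  slots = c(
    codes = "matrix",      # integer category codes, rows x cols
    pixelSize = "numeric", # metres
    epoch = "integer",     # year label of the land-cover epoch
    legend = "character"   # code k -> legend[k]
  )
)

setValidity("LandscapeRaster", function(object) {
  msg <- character()
  cd <- object@codes
  if (!is.numeric(cd) || any(cd != round(cd)) || anyNA(cd))
    msg <- c(msg, "codes must be an integer matrix without NA")
  else {
    if (any(cd < 1L) || any(cd > length(object@legend)))
      msg <- c(msg, "codes must lie within the legend")
    if (length(unique(as.vector(cd))) < 2L)
      msg <- c(msg, "raster must contain at least 2 categories")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' LandscapeRaster: categorical land-cover raster
#'
#' A single-epoch categorical raster on a planar grid. Codes index into the
#' legend (see [landCoverLegend()]).
#'
#' @slot codes integer matrix of category codes (rows x cols).
#' @slot pixelSize pixel edge length in metres (default 20).
#' @slot epoch year label of the land-cover epoch.
#' @slot legend character vector mapping code `k` to a category name.
#' @name LandscapeRaster-class
#' @aliases LandscapeRaster
#' @exportClass LandscapeRaster
NULL

#' Construct a LandscapeRaster
#'
#' @param codes integer matrix of category codes.
#' @param pixelSize pixel edge in metres.
#' @param epoch year label.
#' @param legend category legend; defaults to [landCoverLegend()].
#' @return A [LandscapeRaster-class] object.
#' @export
LandscapeRaster <- function(codes, pixelSize = 20, epoch = 2000L,
                            legend = landCoverLegend()) {
  storage.mode(codes) <- "integer"
  new("LandscapeRaster", codes = codes, pixelSize = as.numeric(pixelSize),
      epoch = as.integer(epoch), legend = legend)
}

#' @rdname ClimateSeries-class
#' @export
setClass("ClimateSeries",
  slots = c(
    cells = "data.frame",  # cell id, lat (and optionally x, y)
    years = "integer",
    summerTemp = "array",  # [cell, year, summer day]
    winterTemp = "array",  # [cell, year, winter day]
    snow = "array",        # [cell, year, winter day], cm
    precip = "array"       # [cell, year, summer day], mm
  )
)

setValidity("ClimateSeries", function(object) {
  msg <- character()
  nc <- nrow(object@cells); ny <- length(object@years)
  dims_ok <- function(a) dim(a)[1] == nc && dim(a)[2] == ny
  if (!all(vapply(list(object@summerTemp, object@winterTemp, object@snow,
                       object@precip), dims_ok, logical(1))))
    msg <- c(msg, "array dimensions must match cells x years")
  if (any(object@snow < 0)) msg <- c(msg, "snow depth must be >= 0")
  if (any(object@precip < 0)) msg <- c(msg, "precipitation must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ClimateSeries: daily climate over cells and years
#'
#' Daily mean temperature, precipitation and snow depth per cell and year
#' over the two season windows used by the covariate summaries: the trap
#' season (1 Apr - 15 Oct, 198 days) and the preceding winter
#' (15 Oct - 1 Apr, 168 days). The windows partition the climate relevant
#' to a trap-year: summer days feed degree-day and precipitation sums,
#' winter days feed chilling and snow summaries.
#'
#' @slot cells data.frame with columns `cell` and `lat`.
#' @slot years integer vector of years.
#' @slot summerTemp,winterTemp numeric arrays `[cell, year, day]`, degrees C.
#' @slot snow numeric array `[cell, year, winter day]`, cm.
#' @slot precip numeric array `[cell, year, summer day]`, mm.
#' @name ClimateSeries-class
#' @aliases ClimateSeries
#' @exportClass ClimateSeries
NULL

#' @rdname TrueParameters-class
#' @export
setClass("TrueParameters",
  slots = c(
    pa = "list",           # B (K x S), Gamma (K x T), Lambda: list per level (H x S)
    ab = "list",           # same structure for the abundance part
    sigma = "numeric",     # per-species abundance residual SD
    covNames = "character",
    blocks = "list",       # named list of design-column indices
    speciesNames = "character",
    traitNames = "character"
  )
)

setValidity("TrueParameters", function(object) {
  msg <- character()
  K <- length(object@covNames); S <- length(object@speciesNames)
  for (part in c("pa", "ab")) {
    p <- slot(object, part)
    if (!all(c("B", "Gamma", "Lambda") %in% names(p))) {
      msg <- c(msg, sprintf("%s must contain B, Gamma, Lambda", part)); next
    }
    if (!all(dim(p$B) == c(K, S)))
      msg <- c(msg, sprintf("%s$B must be covariates x species", part))
    if (nrow(p$Gamma) != K)
      msg <- c(msg, sprintf("%s$Gamma must have one row per covariate", part))
    bad <- vapply(p$Lambda, function(l) ncol(l) != S, logical(1))
    if (any(bad))
      msg <- c(msg, sprintf("%s loadings must have one column per species", part))
  }
  if (length(object@sigma) != S || any(object@sigma <= 0))
    msg <- c(msg, "sigma must be positive, one per species")
  if (length(msg)) msg else TRUE
})

#' TrueParameters: generating parameters of a synthetic community
#'
#' Holds the exact parameters used to simulate a community: species
#' coefficients `B` drawn around the trait regression `Gamma %*% t(traits)`,
#' latent-factor loadings `Lambda` per random level (site, year, zone) and
#' abundance residual SDs `sigma`. Downstream recovery tests compare fitted
#' posteriors against these, and [trueVariancePartition()] computes the
#' ground-truth variance decomposition from them.
#'
#' @slot pa,ab lists with elements `B`, `Gamma`, `Lambda` (and `Omega`,
#'   `effectScales` as metadata) for the presence-absence and abundance
#'   parts.
#' @slot sigma per-species lognormal residual SD (abundance part).
#' @slot covNames,blocks design-matrix column names and block index list.
#' @slot speciesNames,traitNames dimension names.
#' @name TrueParameters-class
#' @aliases TrueParameters
#' @exportClass TrueParameters
NULL

#' @rdname DesignMatrix-class
#' @export
setClass("DesignMatrix",
  slots = c(
    X = "matrix",
    blocks = "list",     # named list: intercept, habitat, climate, effort
    stats = "list",      # per linear covariate: center, scale
    units = "data.frame" # one row per design row: unit ids (site/cell, year)
  )
)

setValidity("DesignMatrix", function(object) {
  msg <- character()
  idx <- sort(unlist(object@blocks, use.names = FALSE))
  if (!identical(idx, seq_len(ncol(object@X))))
    msg <- c(msg, "blocks must partition the design columns")
  if (nrow(object@units) && nrow(object@units) != nrow(object@X))
    msg <- c(msg, "units must have one row per design row")
  if (length(msg)) msg else TRUE
})

#' DesignMatrix: standardized model design with block structure
#'
#' Column layout (20 columns by default): intercept; habitat block = four
#' habitat proportions as linear + quadratic terms plus clumpiness and
#' marginal entropy as linear terms (10 columns); climate block = four
#' climate covariates as linear + quadratic terms (8 columns); effort =
#' log trap-days (1 column). Linear columns are standardized to mean 0 /
#' SD 1 on the training units; quadratic columns are squares of the
#' standardized linear columns; prediction matrices reuse the frozen
#' training statistics.
#'
#' @slot X numeric design matrix.
#' @slot blocks named list of column indices per block.
#' @slot stats standardization statistics (`center`, `scale` per covariate).
#' @slot units data.frame identifying each row (site/cell, year).
#' @name DesignMatrix-class
#' @aliases DesignMatrix
#' @exportClass DesignMatrix
NULL

#' @rdname CommunityTable-class
#' @export
setClass("CommunityTable", contains = "SummarizedExperiment")

setValidity("CommunityTable", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "a 'counts' assay is required")
  else if (any(assay(object, "counts") < 0))
    msg <- c(msg, "counts must be non-negative")
  cd <- colData(object)
  need <- c("site", "year", "effort_days", "zone")
  if (!all(need %in% names(cd)))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(paste(cd$site, cd$year)))
      msg <- c(msg, "duplicate (site, year) units are not allowed")
    if (any(cd$effort_days < 1))
      msg <- c(msg, "effort_days must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' CommunityTable: trap-year by species community matrix
#'
#' A [SummarizedExperiment] with species as rows and trap-year units as
#' columns. The `counts` assay holds annual summed counts; the
#' presence-absence view is `counts > 0` (see [presenceAbsence()]).
#' `colData` carries `site`, `year`, `effort_days`, `zone` and site
#' coordinates.
#'
#' @name CommunityTable-class
#' @aliases CommunityTable-class
#' @exportClass CommunityTable
NULL

#' Construct a CommunityTable
#'
#' @param counts species x unit matrix of annual counts (rownames =
#'   species).
#' @param units data.frame with one row per unit: `site`, `year`,
#'   `effort_days`, `zone` and optionally coordinates (`lat`, `lon`).
#' @return A [CommunityTable-class].
#' @export
CommunityTable <- function(counts, units) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sp", seq_len(nrow(counts)))
  colnames(counts) <- paste(units$site, units$year, sep = "_")
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(units, row.names = colnames(counts)))
  new("CommunityTable", se)
}

#' @rdname PosteriorDraws-class
#' @export
setClass("PosteriorDraws",
  slots = c(
    part = "character",    # "PA" or "AB"
    B = "array",           # [draw, covariate, species]
    Gamma = "array",       # [draw, covariate, trait]
    Omega = "array",       # [draw, covariate, covariate]
    Lambda = "list",       # per level: [draw, factor, species]
    Eta = "list",          # per level: [draw, level unit, factor]
    sigma = "matrix",      # [draw, species]; AB part only (0-col for PA)
    covNames = "character",
    speciesNames = "character",
    blocks = "list",
    levelIds = "list",     # per level: character ids of the level units
    nChains = "integer",
    diagnostics = "list"   # clipped-z count, split-Rhat sample, timings
  )
)

setValidity("PosteriorDraws", function(object) {
  msg <- character()
  if (!object@part %in% c("PA", "AB"))
    msg <- c(msg, "part must be 'PA' or 'AB'")
  d <- dim(object@B)
  if (d[2] != length(object@covNames) || d[3] != length(object@speciesNames))
    msg <- c(msg, "B must be [draw, covariate, species]")
  if (object@part == "AB") {
    if (nrow(object@sigma) != d[1] || any(object@sigma <= 0))
      msg <- c(msg, "sigma must be positive with one row per draw")
  }
  if (length(msg)) msg else TRUE
})

#' PosteriorDraws: retained MCMC draws of one hurdle-model part
#'
#' Arrays of retained Gibbs draws for the presence-absence (`PA`) or
#' abundance (`AB`) part: species coefficients `B`, trait effects `Gamma`,
#' coefficient residual covariance `Omega`, loadings `Lambda` and factor
#' scores `Eta` per random level, and (AB only) residual SDs `sigma`.
#' Draw count = chains x (iterations - burnin) / thin.
#'
#' @slot part `"PA"` or `"AB"`.
#' @slot B,Gamma,Omega posterior draw arrays with the draw as first margin.
#' @slot Lambda,Eta per-level lists of draw arrays.
#' @slot sigma draws x species matrix of abundance residual SDs.
#' @slot covNames,speciesNames,blocks,levelIds dimension metadata.
#' @slot nChains number of chains pooled into the draws.
#' @slot diagnostics list: `clippedZ` (latent clip count), `rhat` (split
#'   R-hat on a sample of B entries), timings.
#' @name PosteriorDraws-class
#' @aliases PosteriorDraws
#' @exportClass PosteriorDraws
NULL

#' @rdname VariancePartitionResult-class
#' @export
setClass("VariancePartitionResult",
  slots = c(
    variances = "array",  # [draw, component, species]
    shares = "array",     # [draw, component, species]
    part = "character",
    negativeFlag = "matrix" # [draw, species]: any negative fixed component
  )
)

setValidity("VariancePartitionResult", function(object) {
  msg <- character()
  if (!identical(dim(object@variances), dim(object@shares)))
    msg <- c(msg, "variances and shares must have identical dimensions")
  if (length(msg)) msg else TRUE
})

#' VariancePartitionResult: per-draw, per-species variance decomposition
#'
#' Component variances and normalized shares of the latent predictor for
#' components habitat, climate and one per random level (site, year, zone).
#' Shares sum to 1 per draw and species. Fixed-effect components may be
#' negative before normalization when covariate blocks are correlated
#' (the symmetric covariance split preserves exact additivity); such
#' draw/species pairs are flagged in `negativeFlag`, not truncated.
#'
#' @slot variances,shares arrays `[draw, component, species]`.
#' @slot part `"PA"`, `"AB"` or `"true"`.
#' @slot negativeFlag logical matrix `[draw, species]`.
#' @name VariancePartitionResult-class
#' @aliases VariancePartitionResult
#' @exportClass VariancePartitionResult
NULL

#' @rdname ContextPartition-class
#' @export
setClass("ContextPartition",
  slots = c(
    contexts = "character",   # label per grid row
    results = "list",         # per context: VariancePartitionResult
    within = "matrix",        # [draw, species] weighted within-context variance
    between = "matrix",       # [draw, species]
    total = "matrix",         # [draw, species] total fixed-predictor variance
    reVariance = "matrix",    # [draw, species] random-effect variance (within)
    part = "character"
  )
)

#' ContextPartition: conditional variance partition by grid context
#'
#' Per-context variance partitions plus the law-of-total-variance split of
#' the fixed predictor into within-context and between-context parts
#' (cell-count weighted). Random-effect variance is constant across cells
#' per species and is assigned wholly to the within component.
#'
#' @slot contexts context label per grid row.
#' @slot results named list of per-context [VariancePartitionResult-class].
#' @slot within,between,total `[draw, species]` matrices; `within + between
#'   == total` per draw/species.
#' @slot reVariance `[draw, species]` random-effect variance.
#' @slot part model part tag.
#' @name ContextPartition-class
#' @aliases ContextPartition
#' @exportClass ContextPartition
NULL

#' @rdname SyntheticStudy-class
#' @export
setClass("SyntheticStudy",
  slots = c(
    community = "CommunityTable",
    covariates = "data.frame",      # raw features per sampled trap-year
    gridCovariates = "data.frame",  # raw features per grid-cell-year
    params = "TrueParameters",
    traits = "data.frame",
    landscape = "list",             # LandscapeRaster per epoch
    seeds = "list",
    config = "list"
  )
)

#' SyntheticStudy: a complete synthetic monitoring study
#'
#' Bundles the simulated community, the raw covariate tables for sampled
#' units and for the prediction grid, species traits, the generating
#' parameters and the configuration used. Sampled sites are a
#' latitude-biased (southern-weighted) subset of grid cells, emulating a
#' non-representative monitoring design; every sampled trap-year has
#' positive effort.
#'
#' @slot community [CommunityTable-class] of simulated counts.
#' @slot covariates,gridCovariates raw feature tables (`hab_*`, `clim_*`,
#'   `effort_days`) for sampled trap-years and grid-cell-years.
#' @slot params [TrueParameters-class] ground truth.
#' @slot traits species trait table (`wing_span`, `host_group`).
#' @slot landscape list of [LandscapeRaster-class], one per epoch.
#' @slot seeds,config generator bookkeeping.
#' @name SyntheticStudy-class
#' @aliases SyntheticStudy
#' @exportClass SyntheticStudy
NULL

#' @rdname DiversitySurface-class
#' @export
setClass("DiversitySurface",
  slots = c(
    cells = "data.frame",  # cell id, lat (and optional coords)
    years = "integer",
    richness = "matrix",   # [cell, year] expected richness
    evenness = "matrix",   # [cell, year] Hill-Simpson evenness
    trends = "data.frame", # cell, metric, mean, slope, variability
    scenario = "character"
  )
)

setValidity("DiversitySurface", function(object) {
  msg <- character()
  nc <- nrow(object@cells); ny <- length(object@years)
  if (!all(dim(object@richness) == c(nc, ny)) ||
      !all(dim(object@evenness) == c(nc, ny)))
    msg <- c(msg, "richness/evenness must be cell x year matrices")
  if (any(object@richness < 0, na.rm = TRUE))
    msg <- c(msg, "richness must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DiversitySurface: community diversity over the prediction grid
#'
#' Expected species richness and Hill-Simpson evenness per grid cell and
#' year, with per-cell linear trend slopes and residual-variability
#' summaries (see [fitCellTrends()]).
#'
#' @slot cells data.frame of grid cells.
#' @slot years integer years.
#' @slot richness,evenness `[cell, year]` matrices.
#' @slot trends long data.frame: `cell`, `metric`, `mean`, `slope`,
#'   `variability`.
#' @slot scenario scenario tag (`full`, `climate_only`, `habitat_only`).
#' @name DiversitySurface-class
#' @aliases DiversitySurface
#' @exportClass DiversitySurface
NULL
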
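## Counterfactual scenario construction, community diversity surfaces and
## per-cell trend/variability maps.

.habCols <- function(covariates) c(
  intersect(c(.habLinear, .habConfig), names(covariates)),
  grep("^comp_", names(covariates), value = TRUE))
.climCols <- function(covariates) intersect(.climLinear, names(covariates))

#' Build a counterfactual covariate scenario
#'
#' `habitat_only` replaces the climate covariates of every cell-year with
#' the cell's average over the first `baselineYears` years (climate held
#' at its early-period state, habitat change acts alone); `climate_only`
#' replaces the habitat covariates with the cell's values in the first
#' year (the first land-cover epoch), so climate change acts alone;
#' `full` returns the table unchanged. Applying a scenario twice equals
#' applying it once.
#'
#' @param covariatesByYear covariate table with `cell`, `year`, habitat
#'   and climate feature columns, covering at least 6 years.
#' @param kind scenario kind.
#' @param baselineYears number of initial years averaged for the climate
#'   baseline (default 5).
#' @return the scenario covariate table (same shape, reordered by cell
#'   within year as supplied).
#' @export
buildScenario <- function(covariatesByYear,
                          kind = c("full", "climate_only", "habitat_only"),
                          baselineYears = 5) {
  kind <- match.arg(kind)
  cov <- covariatesByYear
  years <- sort(unique(cov$year))
  if (kind == "full") return(cov)
  if (length(years) < baselineYears + 1)
    stop("scenario construction needs more years than the baseline window")
  if (kind == "habitat_only") {
    base <- years[seq_len(baselineYears)]
    for (v in .climCols(cov)) {
      baseMean <- tapply(cov[[v]][cov$year %in% base],
                         cov$cell[cov$year %in% base], mean)
      cov[[v]] <- as.vector(baseMean[as.character(cov$cell)])
    }
  } else { # climate_only
    first <- years[1]
    ref <- cov[cov$year == first, ]
    for (v in .habCols(cov)) {
      refVal <- setNames(ref[[v]], ref$cell)
      cov[[v]] <- unname(refVal[as.character(cov$cell)])
    }
  }
  cov
}

#' Expected species richness
#'
#' Sum of occurrence probabilities per community.
#'
#' @param p numeric vector (one community) or units x species matrix of
#'   occurrence probabilities.
#' @return expected richness per community.
#' @export
expectedRichness <- function(p) {
  if (is.matrix(p)) rowSums(p) else sum(p)
}

#' Hill-Simpson evenness
#'
#' Relative abundances `pi_j`, inverse-Simpson (Hill order 2) diversity
#' `D2 = 1 / sum(pi_j^2)`, evenness `D2 / S`. By convention `S` is the
#' number of modelled species (all species have positive expected
#' abundance under the lognormal abundance model); a different richness
#' can be supplied.
#'
#' @param abundances non-negative abundances of one community.
#' @param S species count used in the denominator; default
#'   `length(abundances)`.
#' @return evenness in `(0, 1]`, or `NA` for an all-zero community.
#' @export
#' @examples
#' hillSimpsonEvenness(rep(2, 4))          # 1
#' hillSimpsonEvenness(c(1, 0, 0, 0))      # 0.25
hillSimpsonEvenness <- function(abundances, S = length(abundances)) {
  tot <- sum(abundances)
  if (tot <= 0) return(NA_real_)
  pi <- abundances / tot
  (1 / sum(pi^2)) / S
}

#' Per-cell linear trend and residual variability
#'
#' Fits an independent ordinary least-squares regression of the metric on
#' year within each cell; the trend is the slope, and the variability is
#' the variance of the standardised residuals. Residuals are standardised
#' by the cell's temporal mean of the metric (relative variability), so
#' that the map varies across space; `standardize = "none"` uses raw
#' residuals. A constant series has slope 0 and variability 0.
#'
#' @param values cell x year matrix of the metric.
#' @param years numeric years (>= 3).
#' @param standardize `"cell_mean"` or `"none"`.
#' @return data.frame: `cell` (row index), `mean`, `slope`,
#'   `variability`.
#' @export
fitCellTrends <- function(values, years, standardize = c("cell_mean",
                                                         "none")) {
  standardize <- match.arg(standardize)
  stopifnot(length(years) >= 3, ncol(values) == length(years))
  t0 <- years - mean(years)
  stt <- sum(t0^2)
  mu <- rowMeans(values)
  slope <- as.vector((values %*% t0) / stt)
  fitted <- outer(mu, rep(1, length(years))) + outer(slope, t0)
  resid <- values - fitted
  if (standardize == "cell_mean") {
    denom <- ifelse(mu == 0, NA_real_, mu)
    resid <- resid / denom
  }
  variability <- apply(resid, 1, var)
  constant <- apply(values, 1, function(v) all(v == v[1]))
  slope[constant] <- 0
  variability[constant] <- 0
  data.frame(cell = seq_len(nrow(values)), mean = mu, slope = slope,
             variability = variability)
}

#' Community diversity surface from hurdle predictions
#'
#' Predicts posterior-mean occurrence probabilities and unconditional
#' expected abundances (`p * exp(L_AB + sigma^2/2)`) over the grid
#' covariates (random effects at unobserved grid cells set to zero, so
#' the maps are posterior-expected surfaces), then computes expected
#' richness and Hill-Simpson evenness per cell-year and their per-cell
#' trends.
#'
#' @param paDraws,abDraws fitted [PosteriorDraws-class] objects.
#' @param covariates grid covariate table (`cell`, `year`, features,
#'   `effort_days`).
#' @param stats training standardization statistics (the `stats` of the
#'   training [DesignMatrix-class]).
#' @param scenario tag stored in the result.
#' @param drawIndices posterior draws used for the posterior-mean
#'   predictions (default all).
#' @return a [DiversitySurface-class].
#' @export
diversitySurface <- function(paDraws, abDraws, covariates, stats,
                             scenario = "full", drawIndices = NULL) {
  X <- buildDesignMatrix(covariates, stats = stats)
  units <- covariates[intersect(c("site", "cell", "year", "zone"),
                                names(covariates))]
  pred <- predictHurdle(paDraws, abDraws, X, units = units,
                        reMode = "marginal_zero",
                        drawIndices = drawIndices, summary = TRUE)
  cells <- sort(unique(covariates$cell))
  years <- sort(unique(covariates$year))
  rIdx <- match(covariates$cell, cells)
  cIdx <- match(covariates$year, years)
  rich <- matrix(NA_real_, length(cells), length(years))
  even <- matrix(NA_real_, length(cells), length(years))
  richVec <- expectedRichness(pred$p)
  evenVec <- vapply(seq_len(nrow(pred$p)), function(i)
    hillSimpsonEvenness(pred$abundance[i, ]), numeric(1))
  rich[cbind(rIdx, cIdx)] <- richVec
  even[cbind(rIdx, cIdx)] <- evenVec
  lat <- if ("lat" %in% names(covariates))
    covariates$lat[match(cells, covariates$cell)] else rep(NA_real_,
                                                           length(cells))
  trends <- rbind(
    cbind(metric = "richness", fitCellTrends(rich, years)),
    cbind(metric = "evenness", fitCellTrends(even, years)))
  trends$cell <- cells[trends$cell]
  new("DiversitySurface",
      cells = data.frame(cell = cells, lat = lat),
      years = as.integer(years), richness = rich, evenness = even,
      trends = trends[c("cell", "metric", "mean", "slope", "variability")],
      scenario = scenario)
}

#' Compare scenario diversity surfaces
#'
#' Per-cell differences (scenario minus full) of the temporal mean, trend
#' slope and residual variability of each metric, plus Spearman
#' correlations between each scenario's slope map and the full model's.
#' Purely descriptive; no decision logic.
#'
#' @param full,climateOnly,habitatOnly [DiversitySurface-class] objects
#'   on the same cells and years.
#' @return list: `deltas` (long data.frame: scenario, metric, cell,
#'   dMean, dSlope, dVariability), `slopeCor` (Spearman correlation of
#'   slope maps vs full, per scenario and metric), `summary` (quantiles
#'   of the deltas).
#' @export
scenarioComparison <- function(full, climateOnly, habitatOnly) {
  stopifnot(identical(full@years, climateOnly@years),
            identical(full@years, habitatOnly@years))
  scen <- list(climate_only = climateOnly, habitat_only = habitatOnly)
  deltas <- list(); slopeCor <- list()
  for (s in names(scen)) {
    for (m in c("richness", "evenness")) {
      tf <- full@trends[full@trends$metric == m, ]
      ts <- scen[[s]]@trends[scen[[s]]@trends$metric == m, ]
      stopifnot(identical(tf$cell, ts$cell))
      deltas[[paste(s, m)]] <- data.frame(
        scenario = s, metric = m, cell = tf$cell,
        dMean = ts$mean - tf$mean,
        dSlope = ts$slope - tf$slope,
        dVariability = ts$variability - tf$variability)
      ok <- is.finite(tf$slope) & is.finite(ts$slope)
      slopeCor[[paste(s, m)]] <- data.frame(
        scenario = s, metric = m,
        spearman = if (sum(ok) >= 3) cor(tf$slope[ok], ts$slope[ok],
                                         method = "spearman") else NA_real_)
    }
  }
  deltas <- do.call(rbind, c(deltas, list(make.row.names = FALSE)))
  slopeCor <- do.call(rbind, c(slopeCor, list(make.row.names = FALSE)))
  qs <- aggregate(cbind(dMean, dSlope, dVariability) ~ scenario + metric,
                  deltas, function(x) quantile(x, c(0.025, 0.5, 0.975)))
  list(deltas = deltas, slopeCor = slopeCor, summary = qs)
}
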
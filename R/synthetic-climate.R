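## Synthetic daily climate. The generator produces smooth deterministic
## within-season temperature profiles plus cell-year interannual
## anomalies, a linear latitudinal gradient and a linear warming trend,
## so that the seasonal summaries inherit exactly the structure the
## model's climate covariates assume: a north-south mean gradient,
## year-to-year iid deviations and a slow trend. Summer temperature,
## winter temperature, snowfall and precipitation carry independent
## anomalies (all scaled from `sdInterannual`), so the four covariate
## summaries are correlated only through the shared gradient and trend,
## not deterministically linked.

SUMMER_DAYS <- 198L  # 1 Apr - 15 Oct, the trap season
WINTER_DAYS <- 168L  # 15 Oct - 1 Apr preceding the season

#' Generate daily climate series over cells and years
#'
#' Daily mean temperature (summer and preceding-winter windows), daily
#' precipitation (summer window) and daily snow depth (winter window) per
#' cell and year. Expected summer temperature decreases by `gradient`
#' degrees per unit latitude and increases by `warmingTrend` degrees per
#' year; cell-year interannual deviations are iid normal with SD
#' `sdInterannual`, drawn independently for the summer and winter
#' windows. Snow depth is a non-negative function of daily winter
#' temperature plus a cell-year snowfall anomaly; daily precipitation is
#' a cell-year level with its own anomaly. All anomaly SDs scale with
#' `sdInterannual`, so `sdInterannual = 0` (with `warmingTrend = 0`)
#' makes every year's daily series identical per cell.
#'
#' @param seed integer seed.
#' @param cells data.frame with columns `cell` and `lat`.
#' @param years integer vector of at least 2 years.
#' @param gradient summer cooling in degrees C per unit latitude
#'   northward.
#' @param warmingTrend degrees C per year added to all temperatures.
#' @param sdInterannual SD of cell-year temperature deviations
#'   (degrees C).
#' @param summerMean,summerAmp,winterMean,winterAmp seasonal profile
#'   parameters (degrees C): window mean level and half-range of the
#'   sinusoidal within-window shape.
#' @param precipMean daily precipitation level (mm/day); its cell-year
#'   anomaly has SD `0.25 * sdInterannual`.
#' @param snowSlope cm of snow per degree below 1 C; the snowfall
#'   anomaly has SD `1.5 * snowSlope * sdInterannual` cm.
#' @param latRef reference latitude at which the gradient term is zero.
#' @return a [ClimateSeries-class].
#' @export
generateClimate <- function(seed, cells, years, gradient = 0.4,
                            warmingTrend = 0.04, sdInterannual = 1.0,
                            summerMean = 11, summerAmp = 8,
                            winterMean = -4, winterAmp = 6,
                            precipMean = 1.8, snowSlope = 3,
                            latRef = min(cells$lat)) {
  stopifnot(length(years) >= 2, all(c("cell", "lat") %in% names(cells)))
  set.seed(as.integer(seed))
  nc <- nrow(cells); ny <- length(years)
  latTerm <- -gradient * (cells$lat - latRef)            # per cell
  trend <- warmingTrend * (years - years[1])             # per year
  epsS <- matrix(rnorm(nc * ny, 0, sdInterannual), nc, ny)
  epsW <- matrix(rnorm(nc * ny, 0, sdInterannual), nc, ny)
  epsSnow <- matrix(rnorm(nc * ny, 0, 1.5 * snowSlope * sdInterannual),
                    nc, ny)
  epsP <- matrix(rnorm(nc * ny, 0, 0.25 * sdInterannual), nc, ny)
  # cell-year mean levels
  levS <- outer(latTerm, trend, "+") + summerMean + epsS
  levW <- outer(latTerm, trend, "+") + winterMean + epsW
  shapeS <- summerAmp * sin(pi * (seq_len(SUMMER_DAYS) - 0.5) / SUMMER_DAYS) -
    summerAmp * 2 / pi                                   # mean-zero shape
  shapeW <- -winterAmp * sin(pi * (seq_len(WINTER_DAYS) - 0.5) / WINTER_DAYS) +
    winterAmp * 2 / pi
  summerTemp <- array(rep(levS, SUMMER_DAYS), c(nc, ny, SUMMER_DAYS)) +
    rep(shapeS, each = nc * ny)
  winterTemp <- array(rep(levW, WINTER_DAYS), c(nc, ny, WINTER_DAYS)) +
    rep(shapeW, each = nc * ny)
  snow <- winterTemp
  snow[] <- pmax(0, snowSlope * (1 - winterTemp) +
                   rep(epsSnow, WINTER_DAYS))            # cm
  precip <- array(rep(pmax(0, precipMean + epsP), SUMMER_DAYS),
                  c(nc, ny, SUMMER_DAYS))
  new("ClimateSeries", cells = cells, years = as.integer(years),
      summerTemp = summerTemp, winterTemp = winterTemp,
      snow = snow, precip = precip)
}
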
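## Seasonal climate summaries: the four climate covariates of the model.
## Each operates on one unit's daily series; climateFeatures() maps them
## over a ClimateSeries.

.checkDaily <- function(x, what) {
  if (anyNA(x)) stop("missing days in ", what, " series")
  invisible(x)
}

#' Growing degree-days over the trap season
#'
#' Cumulative sum of daily mean temperature excess over the 5 degree C
#' base, `sum(max(0, T_d - base))`, over the sampling season
#' (1 Apr - 15 Oct).
#'
#' @param dailyTemps numeric vector of daily mean temperatures (degrees C)
#'   covering the season; missing days are an error.
#' @param base reference temperature, degrees C.
#' @return degree-days `>= 0`; zero iff no day exceeds the base.
#' @export
#' @examples
#' growingDegreeDays(c(4, 6, 8))  # 0 + 1 + 3 = 4
growingDegreeDays <- function(dailyTemps, base = 5) {
  .checkDaily(dailyTemps, "temperature")
  sum(pmax(0, dailyTemps - base))
}

#' Chilling degree-days over the preceding winter
#'
#' Sum of daily deficits below the 5 degree C reference,
#' `sum(max(0, base - T_d))`, over the winter window (15 Oct - 1 Apr)
#' preceding the trap season. Reported as a positive chilling sum: larger
#' values mean a colder winter.
#'
#' @inheritParams growingDegreeDays
#' @return degree-days `>= 0`.
#' @export
#' @examples
#' chillingDegreeDays(c(-10, 0, 6))  # 15 + 5 + 0 = 20
chillingDegreeDays <- function(dailyTemps, base = 5) {
  .checkDaily(dailyTemps, "temperature")
  sum(pmax(0, base - dailyTemps))
}

#' Mean winter snow depth
#'
#' Arithmetic mean of daily snow depth over the winter preceding sampling.
#'
#' @param dailySnow numeric vector of daily snow depths (cm).
#' @return cm `>= 0`.
#' @export
winterSnowMean <- function(dailySnow) {
  .checkDaily(dailySnow, "snow")
  mean(dailySnow)
}

#' Cumulative season precipitation
#'
#' Sum of daily precipitation over the trap season (1 Apr - 15 Oct).
#'
#' @param dailyPrecip numeric vector of daily precipitation (mm).
#' @return mm `>= 0`.
#' @export
seasonPrecipitation <- function(dailyPrecip) {
  .checkDaily(dailyPrecip, "precipitation")
  sum(dailyPrecip)
}

#' Map an observation year to its land-cover epoch
#'
#' Year-centred assignment: each observation year maps to the nearest
#' available land-cover epoch, with ties resolved toward the earlier
#' epoch. With the default epochs this reproduces the window mapping
#' 1998-2003 -> 2000, 2004-2009 -> 2006, 2010-2015 -> 2012,
#' 2016-2020 -> 2018.
#'
#' @param year integer vector of observation years.
#' @param epochs available epoch years.
#' @return integer vector of epoch years.
#' @export
#' @examples
#' epochForYear(c(1998, 2003, 2010))
epochForYear <- function(year, epochs = c(2000L, 2006L, 2012L, 2018L)) {
  epochs <- sort(as.integer(epochs))
  vapply(as.integer(year),
         function(y) epochs[which.min(abs(epochs - y))], integer(1))
}

#' Summarise a ClimateSeries into the four climate covariates
#'
#' @param climate a [ClimateSeries-class].
#' @return data.frame with one row per cell-year: `cell`, `year`,
#'   `clim_gdd`, `clim_cdd`, `clim_snow`, `clim_precip`.
#' @export
climateFeatures <- function(climate) {
  stopifnot(is(climate, "ClimateSeries"))
  clamp0 <- function(a) { a[a < 0] <- 0; a }
  gdd <- rowSums(clamp0(climate@summerTemp - 5), dims = 2)
  cdd <- rowSums(clamp0(5 - climate@winterTemp), dims = 2)
  snow <- rowSums(climate@snow, dims = 2) / dim(climate@snow)[3]
  precip <- rowSums(climate@precip, dims = 2)
  ny <- length(climate@years)
  data.frame(
    cell = rep(climate@cells$cell, ny),
    year = rep(climate@years, each = nrow(climate@cells)),
    clim_gdd = as.vector(gdd),
    clim_cdd = as.vector(cdd),
    clim_snow = as.vector(snow),
    clim_precip = as.vector(precip)
  )
}
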
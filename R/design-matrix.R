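## Design-matrix assembly: standardized linear terms, quadratic terms for
## the proportion and climate covariates, linear-only terms for the two
## landscape-configuration metrics, and a raw log-effort column.

.habLinear <- c("hab_broadleaf", "hab_conifer", "hab_mixed", "hab_seminatural")
.habConfig <- c("hab_clumpiness", "hab_entropy")
.climLinear <- c("clim_gdd", "clim_cdd", "clim_snow", "clim_precip")
.quadCovs <- function() c(.habLinear, .climLinear)

#' Feature column names expected by the design-matrix builder
#' @return character vector of the ten covariate columns plus
#'   `effort_days`.
#' @export
covariateColumns <- function() c(.habLinear, .habConfig, .climLinear,
                                 "effort_days")

#' Build the standardized model design matrix
#'
#' Expands a raw covariate table into the 20-column model design: an
#' intercept; the habitat block (four habitat proportions as standardized
#' linear plus quadratic terms, clumpiness and marginal entropy as
#' standardized linear terms: 10 columns); the climate block (four climate
#' covariates as standardized linear plus quadratic terms: 8 columns); and
#' log trap-days effort as an unstandardized linear column. Quadratic
#' columns are the squares of the standardized linear columns.
#'
#' Standardization statistics are computed on the supplied units (the
#' training trap-years) and frozen in the result; pass them back via
#' `stats` to build prediction-grid matrices on the training scale. A
#' covariate with zero variance on the training units is an error naming
#' the column. Units with an undefined clumpiness value (`NA`, from a
#' window with no or only forest) are excluded from the statistics and
#' mean-imputed (standardized value 0) with a warning.
#'
#' @param covariates data.frame with the columns of [covariateColumns()]
#'   plus unit identifiers (any of `site`, `cell`, `year` are carried
#'   through).
#' @param stats `NULL` to compute standardization on these units, or the
#'   `stats` element of a training [DesignMatrix-class].
#' @return a [DesignMatrix-class] with blocks `intercept`, `habitat`,
#'   `climate`, `effort`.
#' @export
buildDesignMatrix <- function(covariates, stats = NULL) {
  need <- covariateColumns()
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("missing covariate columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(covariates)
  linCovs <- c(.habLinear, .habConfig, .climLinear)
  raw <- as.matrix(covariates[linCovs])
  if (anyNA(raw[, setdiff(linCovs, "hab_clumpiness")]))
    stop("missing values in covariates other than clumpiness")
  if (is.null(stats)) {
    if (anyNA(raw[, "hab_clumpiness"]))
      warning("units with undefined clumpiness dropped from standardization")
    center <- colMeans(raw, na.rm = TRUE)
    scale <- apply(raw, 2, sd, na.rm = TRUE)
    zero <- names(scale)[is.na(scale) | scale == 0]
    if (length(zero)) stop("zero-variance covariate: ",
                           paste(zero, collapse = ", "))
    stats <- list(center = center, scale = scale)
  }
  z <- sweep(sweep(raw, 2, stats$center[linCovs]), 2,
             stats$scale[linCovs], "/")
  z[is.na(z)] <- 0  # mean-imputed undefined clumpiness
  cols <- list(intercept = rep(1, n))
  for (v in c(.habLinear)) {
    cols[[v]] <- z[, v]
    cols[[paste0(v, "_sq")]] <- z[, v]^2
  }
  for (v in .habConfig) cols[[v]] <- z[, v]
  for (v in .climLinear) {
    cols[[v]] <- z[, v]
    cols[[paste0(v, "_sq")]] <- z[, v]^2
  }
  cols[["effort_logdays"]] <- log(covariates$effort_days)
  X <- do.call(cbind, cols)
  nm <- colnames(X)
  blocks <- list(
    intercept = which(nm == "intercept"),
    habitat = which(nm %in% c(paste0(rep(.habLinear, each = 2),
                                     c("", "_sq")), .habConfig)),
    climate = which(nm %in% paste0(rep(.climLinear, each = 2), c("", "_sq"))),
    effort = which(nm == "effort_logdays")
  )
  idcols <- intersect(c("site", "cell", "year"), names(covariates))
  units <- if (length(idcols)) covariates[idcols] else
    data.frame(row = seq_len(n))
  new("DesignMatrix", X = X, blocks = blocks, stats = stats, units = units)
}
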
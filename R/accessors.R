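## Accessors and show methods. Slot access from user code should go
## through these.

#' @name accessors
#' @title Accessors for jsdmVP classes
#' @description Small accessor generics: counts and presence-absence views
#'   of a [CommunityTable-class], posterior summaries of
#'   [PosteriorDraws-class], and share arrays of
#'   [VariancePartitionResult-class].
#' @param object an object of the documented class.
#' @param x an object of the documented class.
#' @param what slot-like quantity to summarise (`"B"`, `"Gamma"`,
#'   `"sigma"`).
NULL

#' @rdname accessors
#' @export
setGeneric("presenceAbsence", function(object) standardGeneric("presenceAbsence"))

#' @rdname accessors
#' @export
setMethod("presenceAbsence", "CommunityTable", function(object) {
  assay(object, "counts") > 0
})

#' @rdname accessors
#' @export
setGeneric("effortDays", function(object) standardGeneric("effortDays"))

#' @rdname accessors
#' @export
setMethod("effortDays", "CommunityTable", function(object) colData(object)$effort_days)

#' @rdname accessors
#' @export
setGeneric("nDraws", function(object) standardGeneric("nDraws"))

#' @rdname accessors
#' @export
setMethod("nDraws", "PosteriorDraws", function(object) dim(object@B)[1])

#' @rdname accessors
#' @export
setGeneric("posteriorMean", function(object, what = "B") standardGeneric("posteriorMean"))

#' @rdname accessors
#' @export
setMethod("posteriorMean", "PosteriorDraws", function(object, what = "B") {
  a <- slot(object, what)
  if (is.matrix(a)) colMeans(a) else apply(a, c(2, 3), mean)
})

#' @rdname accessors
#' @export
setGeneric("vpShares", function(object) standardGeneric("vpShares"))

#' @rdname accessors
#' @export
setMethod("vpShares", "VariancePartitionResult", function(object) object@shares)

#' @rdname accessors
#' @export
setGeneric("vpVariances", function(object) standardGeneric("vpVariances"))

#' @rdname accessors
#' @export
setMethod("vpVariances", "VariancePartitionResult", function(object) object@variances)

#' Summarise a variance partition
#'
#' Posterior median and central 95% interval of each component share per
#' species.
#'
#' @param object a [VariancePartitionResult-class].
#' @return data.frame with `species`, `component`, `median`, `q2.5`,
#'   `q97.5`.
#' @export
vpSummary <- function(object) {
  stopifnot(is(object, "VariancePartitionResult"))
  sh <- object@shares
  comps <- dimnames(sh)[[2]]; spp <- dimnames(sh)[[3]]
  out <- expand.grid(component = comps, species = spp,
                     stringsAsFactors = FALSE)[, 2:1]
  qs <- apply(sh, c(2, 3), quantile, probs = c(0.5, 0.025, 0.975))
  out$median <- as.vector(qs[1, , ])
  out$q2.5 <- as.vector(qs[2, , ])
  out$q97.5 <- as.vector(qs[3, , ])
  out
}

setMethod("show", "LandscapeRaster", function(object) {
  cat("LandscapeRaster:", nrow(object@codes), "x", ncol(object@codes),
      "pixels at", object@pixelSize, "m, epoch", object@epoch, "\n")
  tab <- table(factor(object@legend[object@codes], levels = object@legend))
  props <- round(tab / sum(tab), 3)
  cat("  cover:", paste(names(props), props, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ClimateSeries", function(object) {
  cat("ClimateSeries:", nrow(object@cells), "cells x", length(object@years),
      "years; summer", dim(object@summerTemp)[3], "d, winter",
      dim(object@winterTemp)[3], "d\n")
})

setMethod("show", "TrueParameters", function(object) {
  cat("TrueParameters:", length(object@speciesNames), "species,",
      length(object@covNames), "covariates,",
      length(object@traitNames), "trait columns\n")
  cat("  factors per level:",
      paste(names(object@pa$Lambda),
            vapply(object@pa$Lambda, nrow, integer(1)),
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix:", nrow(object@X), "units x", ncol(object@X), "columns\n")
  cat("  blocks:", paste(names(object@blocks),
      vapply(object@blocks, length, integer(1)), sep = "=", collapse = ", "),
      "\n")
})

setMethod("show", "CommunityTable", function(object) {
  cat("CommunityTable:", nrow(object), "species x", ncol(object),
      "trap-years\n")
  pa <- presenceAbsence(object)
  cat("  prevalence range:",
      paste(round(range(rowMeans(pa)), 3), collapse = " - "), "\n")
  callNextMethod()
})

setMethod("show", "PosteriorDraws", function(object) {
  cat("PosteriorDraws [", object@part, "]: ", nDraws(object), " draws (",
      object@nChains, " chains), ", length(object@covNames),
      " covariates x ", length(object@speciesNames), " species\n", sep = "")
  if (length(object@Lambda))
    cat("  random levels:", paste(names(object@Lambda), collapse = ", "), "\n")
})

setMethod("show", "VariancePartitionResult", function(object) {
  d <- dim(object@shares)
  cat("VariancePartitionResult [", object@part, "]: ", d[1], " draws x ",
      d[2], " components x ", d[3], " species\n", sep = "")
  m <- apply(object@shares, 2, mean)
  cat("  mean shares:", paste(names(m), round(m, 3), sep = "=",
      collapse = ", "), "\n")
})

setMethod("show", "ContextPartition", function(object) {
  cat("ContextPartition [", object@part, "]: ",
      length(object@results), " contexts (",
      paste(names(object@results), collapse = ", "), ")\n", sep = "")
  ws <- mean(object@within / object@total, na.rm = TRUE)
  cat("  mean within-share of fixed variance:", round(ws, 3), "\n")
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy:", nrow(object@community), "species,",
      ncol(object@community), "trap-years,",
      length(unique(object@gridCovariates$cell)), "grid cells,",
      length(unique(object@gridCovariates$year)), "years\n")
})

setMethod("show", "DiversitySurface", function(object) {
  cat("DiversitySurface [", object@scenario, "]: ", nrow(object@cells),
      " cells x ", length(object@years), " years\n", sep = "")
  cat("  mean richness:", round(mean(object@richness), 2),
      " mean evenness:", round(mean(object@evenness, na.rm = TRUE), 3), "\n")
})
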
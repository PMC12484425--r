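## Plain-text interchange: CSV tables, YAML configs, and (optionally,
## via the tiff package) integer land-cover rasters with a legend
## sidecar.

#' Write a community table to CSV
#'
#' One row per trap-year: unit metadata columns followed by one count
#' column per species.
#'
#' @param community a [CommunityTable-class].
#' @param path output CSV path.
#' @export
writeCommunityCSV <- function(community, path) {
  cd <- as.data.frame(colData(community))
  cnt <- t(assay(community, "counts"))
  write.csv(cbind(cd, cnt), path, row.names = FALSE)
}

#' Read a community table written by [writeCommunityCSV()]
#'
#' @param path CSV path.
#' @param speciesPrefix regular expression identifying species columns
#'   (default: columns named `sp` followed by digits).
#' @return a [CommunityTable-class].
#' @export
readCommunityCSV <- function(path, speciesPrefix = "^sp[0-9]+$") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  spCols <- grep(speciesPrefix, names(df), value = TRUE)
  CommunityTable(t(as.matrix(df[spCols])), df[setdiff(names(df), spCols)])
}

#' Write a variance partition to long and summary CSV
#'
#' @param vp a [VariancePartitionResult-class].
#' @param longPath per-draw long CSV (`draw`, `species`, `component`,
#'   `variance`, `share`); skipped if `NULL`.
#' @param summaryPath per-species summary CSV (median and 95% interval of
#'   each share).
#' @export
writeVPResult <- function(vp, longPath = NULL, summaryPath) {
  if (!is.null(longPath)) {
    d <- dim(vp@variances)
    dn <- dimnames(vp@variances)
    long <- expand.grid(draw = seq_len(d[1]), component = dn[[2]],
                        species = dn[[3]], stringsAsFactors = FALSE)
    long$variance <- as.vector(vp@variances)
    long$share <- as.vector(vp@shares)
    write.csv(long[c("draw", "species", "component", "variance", "share")],
              longPath, row.names = FALSE)
  }
  write.csv(vpSummary(vp), summaryPath, row.names = FALSE)
}

#' Write a land-cover raster as an 8-bit TIFF with a legend sidecar
#'
#' Integer category codes are stored in an 8-bit grayscale TIFF (code k
#' as gray level k/255) and the legend as `<path>.legend.csv`. Requires
#' the `tiff` package.
#'
#' @param raster a [LandscapeRaster-class].
#' @param path output TIFF path.
#' @export
writeLandscapeTIFF <- function(raster, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for raster output")
  tiff::writeTIFF(raster@codes / 255, path, bits.per.sample = 8)
  write.csv(data.frame(code = seq_along(raster@legend),
                       category = raster@legend,
                       pixel_size = raster@pixelSize,
                       epoch = raster@epoch),
            paste0(path, ".legend.csv"), row.names = FALSE)
}

#' Read a land-cover raster written by [writeLandscapeTIFF()]
#' @param path TIFF path (the legend sidecar must sit beside it).
#' @return a [LandscapeRaster-class].
#' @export
readLandscapeTIFF <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for raster input")
  codes <- round(tiff::readTIFF(path) * 255)
  leg <- read.csv(paste0(path, ".legend.csv"), stringsAsFactors = FALSE)
  LandscapeRaster(codes, pixelSize = leg$pixel_size[1],
                  epoch = leg$epoch[1], legend = leg$category)
}

#' Write diversity surfaces to long CSV
#'
#' @param surface a [DiversitySurface-class].
#' @param valuesPath long CSV of cell x year richness and evenness.
#' @param trendsPath per-cell trend/variability CSV.
#' @export
writeDiversityCSV <- function(surface, valuesPath, trendsPath) {
  ny <- length(surface@years)
  long <- data.frame(
    scenario = surface@scenario,
    cell = rep(surface@cells$cell, ny),
    year = rep(surface@years, each = nrow(surface@cells)),
    richness = as.vector(surface@richness),
    evenness = as.vector(surface@evenness))
  write.csv(long, valuesPath, row.names = FALSE)
  tr <- cbind(scenario = surface@scenario, surface@trends)
  write.csv(tr, trendsPath, row.names = FALSE)
}

# Small stable content hash (Adler-style checksum over serialized
# bytes), for run manifests; not cryptographic.
.contentHash <- function(x) {
  bytes <- if (is.raw(x)) x else serialize(x, NULL, version = 2)
  b <- as.double(bytes)
  s1 <- sum(b) %% 65521
  s2 <- sum(b * (seq_along(b) %% 5552)) %% 65521
  sprintf("%04x%04x", s2, s1)
}

.fileHash <- function(path) {
  .contentHash(readBin(path, "raw", n = file.info(path)$size))
}

#' Persist posterior coefficient draws to long CSV
#'
#' Writes the species-coefficient draws (and, for the abundance part,
#' residual SDs) in long format: `draw`, `covariate`, `species`, `value`
#' plus `sigma` rows keyed by species.
#'
#' @param draws a [PosteriorDraws-class].
#' @param path output CSV path.
#' @export
writePosteriorDraws <- function(draws, path) {
  d <- dim(draws@B)
  long <- expand.grid(draw = seq_len(d[1]), covariate = draws@covNames,
                      species = draws@speciesNames,
                      stringsAsFactors = FALSE)
  long$parameter <- "B"
  long$value <- as.vector(draws@B)
  if (draws@part == "AB") {
    sg <- expand.grid(draw = seq_len(d[1]), covariate = NA_character_,
                      species = draws@speciesNames,
                      stringsAsFactors = FALSE)
    sg$parameter <- "sigma"
    sg$value <- as.vector(draws@sigma)
    long <- rbind(long, sg)
  }
  write.csv(long, path, row.names = FALSE)
}
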
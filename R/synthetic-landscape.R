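## Synthetic land-cover generation. Classes are carved out of smoothed
## Gaussian random fields so that they form spatial clusters; a second,
## independent field controls water/wetland so that aquatic cover crosses
## the terrestrial mosaic the way lakes cross managed forest.

# Circularly smooth a white-noise field with a Gaussian kernel of the
# given standard deviation (in pixels).
.smoothField <- function(rows, cols, scale) {
  if (scale <= 0) stop("autocorrScale must be > 0")
  noise <- matrix(rnorm(rows * cols), rows, cols)
  half <- max(1L, ceiling(3 * scale))
  kern <- dnorm(seq(-half, half), sd = scale)
  kern <- kern / sum(kern)
  sm <- stats::filter(noise, kern, circular = TRUE)        # down columns
  sm <- t(stats::filter(t(sm), kern, circular = TRUE))     # along rows
  matrix(as.numeric(sm), rows, cols)
}

# Slice a terrestrial field and a wetness field into the 8-class legend.
.classifyFields <- function(land, wet,
                            terrestrialProps = c(broadleaf_forest = 0.07,
                                                 coniferous_forest = 0.38,
                                                 mixed_forest = 0.15,
                                                 seminatural_herbaceous = 0.13,
                                                 urban = 0.05,
                                                 agriculture = 0.22),
                            waterProp = 0.06, wetlandProp = 0.06) {
  legend <- landCoverLegend()
  edges <- quantile(land, cumsum(terrestrialProps)[-length(terrestrialProps)])
  cls <- findInterval(land, edges) + 1L  # 1..6 terrestrial order
  codeOf <- match(names(terrestrialProps), legend)
  codes <- matrix(codeOf[cls], nrow(land), ncol(land))
  wq <- quantile(wet, c(1 - waterProp - wetlandProp, 1 - waterProp))
  codes[wet > wq[1] & wet <= wq[2]] <- match("wetland", legend)
  codes[wet > wq[2]] <- match("water", legend)
  codes
}

#' Generate a spatially clustered land-cover raster series
#'
#' Generates one categorical raster per land-cover epoch by thresholding
#' smoothed Gaussian random fields: one field is quantile-sliced into the
#' six terrestrial categories and an independent field assigns the top
#' wetness quantiles to wetland and water. Between consecutive epochs a
#' uniformly random subset of at most `changeRate` of the pixels is
#' re-drawn from a fresh field pair, emulating gradual land-cover change
#' between mapping epochs.
#'
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @param rows,cols raster dimensions in pixels (both >= 32).
#' @param nEpochs number of land-cover epochs.
#' @param autocorrScale Gaussian smoothing SD in pixels; larger values give
#'   larger, more aggregated patches. Must be positive.
#' @param changeRate fraction of pixels eligible to change between
#'   consecutive epochs, in `[0, 1)`.
#' @param pixelSize pixel edge length in metres.
#' @param epochs year labels, default 2000, 2006, ...
#' @return list of [LandscapeRaster-class], one per epoch.
#' @export
#' @examples
#' ls1 <- generateLandscape(1, rows = 48, cols = 48, nEpochs = 2)
#' ls1[[1]]
generateLandscape <- function(seed, rows, cols, nEpochs = 1,
                              autocorrScale = 4, changeRate = 0.05,
                              pixelSize = 20,
                              epochs = seq(2000L, by = 6L,
                                           length.out = nEpochs)) {
  stopifnot(rows >= 32, cols >= 32, changeRate >= 0, changeRate < 1,
            nEpochs >= 1, length(epochs) == nEpochs)
  if (autocorrScale <= 0) stop("autocorrScale must be > 0")
  set.seed(as.integer(seed))
  codes <- .classifyFields(.smoothField(rows, cols, autocorrScale),
                           .smoothField(rows, cols, autocorrScale))
  out <- vector("list", nEpochs)
  out[[1]] <- LandscapeRaster(codes, pixelSize, epochs[1])
  if (nEpochs > 1) {
    for (e in 2:nEpochs) {
      prev <- out[[e - 1]]@codes
      if (changeRate > 0) {
        fresh <- .classifyFields(.smoothField(rows, cols, autocorrScale),
                                 .smoothField(rows, cols, autocorrScale))
        flip <- runif(rows * cols) < changeRate
        nxt <- prev
        nxt[flip] <- fresh[flip]
      } else {
        nxt <- prev
      }
      out[[e]] <- LandscapeRaster(nxt, pixelSize, epochs[e])
    }
  }
  out
}

#' Rook like-adjacency fraction of a categorical raster
#'
#' Fraction of ordered rook-neighbour pixel pairs whose two pixels share a
#' category; a scalar summary of spatial aggregation used to verify that
#' the landscape generator produces clustered classes.
#'
#' @param codes integer matrix of category codes.
#' @return fraction in `[0, 1]`.
#' @export
likeAdjacencyFraction <- function(codes) {
  horiz <- codes[, -ncol(codes), drop = FALSE] == codes[, -1, drop = FALSE]
  vert <- codes[-nrow(codes), , drop = FALSE] == codes[-1, , drop = FALSE]
  (sum(horiz) + sum(vert)) / (length(horiz) + length(vert))
}
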
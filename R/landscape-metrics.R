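## Landscape metrics over square buffers: habitat-category proportions,
## clumpiness of the merged forest mask, and marginal entropy. All three
## operate on a pixel window cut from a LandscapeRaster.

# Resolve a window specification to a sub-matrix of codes.
# window: NULL (whole raster) or list(rows =, cols =) of index ranges.
.windowCodes <- function(raster, window) {
  stopifnot(is(raster, "LandscapeRaster"))
  if (is.null(window)) return(raster@codes)
  raster@codes[window$rows, window$cols, drop = FALSE]
}

#' Habitat-category proportions in a square buffer
#'
#' Fractions of each legend category among the pixels whose centres fall in
#' the square window of side `bufferSide` centred on `center` (planar
#' coordinates in metres, origin at the raster's top-left corner; x runs
#' along columns, y along rows). A buffer partially outside the raster is
#' evaluated over the intersection with a warning; a buffer fully outside
#' is an error.
#'
#' @param raster a [LandscapeRaster-class].
#' @param center numeric `c(x, y)` in metres.
#' @param bufferSide buffer edge length in metres (default 500, i.e. the
#'   25 ha landscape window).
#' @return named numeric vector over the full legend, summing to 1.
#' @export
bufferProportions <- function(raster, center, bufferSide = 500) {
  stopifnot(is(raster, "LandscapeRaster"), length(center) == 2)
  ps <- raster@pixelSize
  half <- bufferSide / 2
  nr <- nrow(raster@codes); nc <- ncol(raster@codes)
  # pixel (i, j) has centre x = (j - 0.5) ps, y = (i - 0.5) ps
  jr <- range(which(abs((seq_len(nc) - 0.5) * ps - center[1]) <= half))
  ir <- range(which(abs((seq_len(nr) - 0.5) * ps - center[2]) <= half))
  if (any(!is.finite(c(ir, jr))))
    stop("buffer lies fully outside the raster")
  fullPix <- round(bufferSide / ps)^2
  win <- raster@codes[ir[1]:ir[2], jr[1]:jr[2], drop = FALSE]
  if (length(win) < fullPix)
    warning("buffer partially outside raster; proportions over intersection")
  tab <- tabulate(win, nbins = length(raster@legend))
  setNames(tab / sum(tab), raster@legend)
}

# Ordered rook adjacency counts for a logical mask: returns c(like, total)
# where `total` counts every adjacency involving a TRUE pixel from the
# TRUE side (double-count convention: each unordered pair contributes one
# count per TRUE endpoint).
.maskAdjacency <- function(mask) {
  like <- 0L; total <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  if (nc > 1) {
    a <- mask[, -nc, drop = FALSE]; b <- mask[, -1, drop = FALSE]
    like <- like + 2L * sum(a & b)
    total <- total + sum(a) + sum(b)  # each horizontal pair, per TRUE endpoint
  }
  if (nr > 1) {
    a <- mask[-nr, , drop = FALSE]; b <- mask[-1, , drop = FALSE]
    like <- like + 2L * sum(a & b)
    total <- total + sum(a) + sum(b)
  }
  c(like = like, total = total)
}

#' Clumpiness index of the forest mask
#'
#' Aggregation metric in `[-1, 1]` of the focal class (by default the
#' union of the three forest categories) within a window: with `P` the
#' focal-class proportion and `G` the like-adjacency fraction
#' `g_ii / sum_k g_ik` under rook adjacency with the double-count
#' convention, the index is `(G - P) / P` when `G < P` and `P < 0.5`, and
#' `(G - P) / (1 - P)` otherwise. -1 is maximal disaggregation (a
#' checkerboard), +1 maximal clumping, and a spatially random mask is near
#' 0.
#'
#' Windows where the focal class covers no pixel or every pixel have no
#' defined adjacency structure; these return `NA` and should be dropped
#' (with a warning) from covariate standardization.
#'
#' @param raster a [LandscapeRaster-class].
#' @param window `NULL` for the whole raster, or `list(rows =, cols =)`
#'   index ranges.
#' @param focalClasses integer codes forming the focal mask; defaults to
#'   [forestCodes()].
#' @return numeric in `[-1, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' chk <- matrix(rep_len(c(1L, 6L), 64), 8, 8)  # checkerboard
#' r <- LandscapeRaster(chk)
#' clumpiness(r)  # -1
clumpiness <- function(raster, window = NULL, focalClasses = forestCodes()) {
  win <- .windowCodes(raster, window)
  if (length(win) == 0) stop("empty window")
  mask <- matrix(win %in% focalClasses, nrow(win), ncol(win))
  P <- mean(mask)
  if (P == 0 || P == 1) return(NA_real_)
  adj <- .maskAdjacency(mask)
  if (adj["total"] == 0) return(NA_real_)
  G <- unname(adj["like"] / adj["total"])
  if (G < P && P < 0.5) (G - P) / P else (G - P) / (1 - P)
}

#' Marginal entropy of land-cover composition
#'
#' Shannon entropy `-sum p_k log(p_k)` of the category proportions in a
#' window, with `0 log 0 = 0`. Base 2 (bits) by default, matching the
#' common landscape-metrics convention; the base is configurable.
#'
#' @inheritParams clumpiness
#' @param base logarithm base (2 = bits).
#' @return entropy `>= 0`; at most `log(K, base)` for `K` observed
#'   categories.
#' @export
marginalEntropy <- function(raster, window = NULL, base = 2) {
  win <- .windowCodes(raster, window)
  if (length(win) == 0) stop("empty window")
  p <- tabulate(win, nbins = max(win)) / length(win)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}
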
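## Predictive variance partitioning over a prediction grid, conditional
## variants by environmental and functional context, and the
## dominant-driver summary.

# Population covariance (1/n denominator), so that the within/between
# decomposition and the group additivity identities hold exactly.
.popCov <- function(X) {
  n <- nrow(X)
  cov(X) * (n - 1) / n
}

# Validate that `groups` partitions the non-intercept, non-effort design
# columns; returns the named list of column indices.
.vpGroups <- function(blocks, groups, nCol) {
  if (is.null(groups))
    groups <- blocks[setdiff(names(blocks), c("intercept", "effort"))]
  target <- sort(unlist(blocks[setdiff(names(blocks),
                                       c("intercept", "effort"))],
                        use.names = FALSE))
  got <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(got) || !identical(sort(got), target))
    stop("groups must partition the non-intercept, non-effort design columns")
  groups
}

# Core decomposition shared by the posterior and ground-truth variants.
# getB(d): K x S coefficient matrix of draw d over *all* design columns;
# lambdas: list per level of function(d) -> H x S loadings.
.vpCore <- function(nd, getB, lambdas, Xgrid, groups, species, part) {
  cols <- unlist(groups, use.names = FALSE)
  C <- .popCov(Xgrid[, cols, drop = FALSE])
  S <- length(species)
  comps <- c(names(groups), names(lambdas))
  V <- array(0, c(nd, length(comps), S),
             dimnames = list(NULL, comps, species))
  for (d in seq_len(nd)) {
    B <- getB(d)[cols, , drop = FALSE]
    M <- C %*% B
    for (g in names(groups)) {
      ix <- match(groups[[g]], cols)
      V[d, g, ] <- colSums(B[ix, , drop = FALSE] * M[ix, , drop = FALSE])
    }
    for (r in names(lambdas)) {
      L <- lambdas[[r]](d)
      V[d, r, ] <- if (nrow(L)) colSums(L^2) else 0
    }
  }
  tot <- apply(V, c(1, 3), sum)
  shares <- V
  for (i in seq_along(comps)) shares[, i, ] <- V[, i, ] / tot
  neg <- apply(V[, names(groups), , drop = FALSE] < 0, c(1, 3), any)
  new("VariancePartitionResult", variances = V, shares = shares,
      part = part, negativeFlag = neg)
}

#' Predictive variance partitioning over a prediction grid
#'
#' Decomposes, per posterior draw and species, the variance of the latent
#' predictor over the grid units into a habitat component, a climate
#' component and one component per random level. Fixed components use the
#' empirical (population) covariance `C` of the design columns over the
#' grid: `V_g = sum_{k in g} B_kj (C B_j)_k`, which splits cross-group
#' covariance symmetrically and sums exactly to the total fixed-predictor
#' variance (individual components can therefore be negative under
#' correlated blocks; they are flagged, not truncated). Random-level
#' components are `sum_h lambda_{r,h,j}^2`. The intercept and effort
#' columns are excluded (effort is held constant over the grid, so it
#' contributes no variance); the probit unit residual and the abundance
#' residual are likewise outside the partition, which covers explained
#' variation only.
#'
#' @param draws a [PosteriorDraws-class].
#' @param Xgrid the prediction-grid [DesignMatrix-class] (built with the
#'   training standardization); grid-cell-years are pooled across years,
#'   so temporal climate variation contributes to the climate component.
#' @param groups named list of design-column indices; default = the
#'   habitat and climate blocks. Must partition the non-intercept,
#'   non-effort columns.
#' @return a [VariancePartitionResult-class].
#' @export
variancePartition <- function(draws, Xgrid, groups = NULL) {
  stopifnot(is(draws, "PosteriorDraws"))
  groups <- .vpGroups(draws@blocks, groups, ncol(Xgrid@X))
  S <- length(draws@speciesNames)
  lambdas <- lapply(names(draws@Lambda), function(r) {
    H <- dim(draws@Lambda[[r]])[2]
    function(d) matrix(draws@Lambda[[r]][d, , ], H, S)
  })
  names(lambdas) <- names(draws@Lambda)
  .vpCore(nDraws(draws), function(d) matrix(draws@B[d, , ],
                                            ncol = S),
          lambdas, Xgrid@X, groups, draws@speciesNames, draws@part)
}

#' Ground-truth variance partition from generating parameters
#'
#' The same decomposition as [variancePartition()] computed from the true
#' `B` and `Lambda` of a [TrueParameters-class]; the oracle for recovery
#' tests.
#'
#' @param params a [TrueParameters-class].
#' @param Xgrid the prediction-grid [DesignMatrix-class].
#' @param part `"pa"` or `"ab"`.
#' @inheritParams variancePartition
#' @return a [VariancePartitionResult-class] with a single draw.
#' @export
trueVariancePartition <- function(params, Xgrid, part = c("pa", "ab"),
                                  groups = NULL) {
  stopifnot(is(params, "TrueParameters"))
  part <- match.arg(part)
  p <- slot(params, part)
  groups <- .vpGroups(params@blocks, groups, ncol(Xgrid@X))
  lambdas <- lapply(p$Lambda, function(L) function(d) L)
  .vpCore(1L, function(d) p$B, lambdas, Xgrid@X, groups,
          params@speciesNames, "true")
}

#' Cluster grid cells into dominant-habitat profiles
#'
#' k-means on the full land-cover composition of each grid cell (all
#' categories, not only the model covariates). Profiles are named by any
#' category whose cluster-mean proportion exceeds 0.5, else
#' `heterogeneous` (suffixed when several clusters share a name).
#'
#' @param composition cells x categories matrix of proportions.
#' @param k number of profiles.
#' @param nRestarts k-means restarts.
#' @param seed integer seed; fixed seed and restarts give identical
#'   labels.
#' @return list: `labels` (profile name per cell), `centers` (profile
#'   mean composition), `cluster` (integer assignment).
#' @export
kmeansProfiles <- function(composition, k = 4, nRestarts = 10, seed = 1) {
  composition <- as.matrix(composition)
  if (k > nrow(composition)) stop("more clusters than cells")
  if (nrow(unique(composition)) < k)
    stop("fewer distinct compositions than clusters (empty cluster)")
  set.seed(as.integer(seed))
  km <- kmeans(composition, centers = k, nstart = nRestarts, iter.max = 50)
  nameOf <- apply(km$centers, 1, function(ctr) {
    dom <- names(ctr)[ctr > 0.5]
    if (length(dom)) dom[which.max(ctr[dom])] else "heterogeneous"
  })
  nameOf <- make.unique(nameOf, sep = "_")
  list(labels = nameOf[km$cluster], centers = km$centers,
       cluster = km$cluster)
}

#' Conditional variance partitioning by environmental context
#'
#' Restricts the predictive variance partition to each context (a
#' labelling of the grid rows, e.g. k-means habitat profiles) and
#' decomposes the total fixed-predictor variance into within-context and
#' between-context parts by the law of total variance with cell-count
#' weights. Random-effect variance does not vary across cells within a
#' species and is assigned wholly to the within component. Contexts with
#' fewer than 2 rows are excluded from the per-context partitions with a
#' warning (their within-variance is undefined) but still enter the
#' within/between decomposition.
#'
#' @param draws a [PosteriorDraws-class].
#' @param Xgrid the prediction-grid [DesignMatrix-class].
#' @param contexts character/factor label per grid row.
#' @param groups as in [variancePartition()].
#' @return a [ContextPartition-class].
#' @export
conditionalVPEnvironmental <- function(draws, Xgrid, contexts,
                                       groups = NULL) {
  stopifnot(is(draws, "PosteriorDraws"), length(contexts) == nrow(Xgrid@X))
  groups <- .vpGroups(draws@blocks, groups, ncol(Xgrid@X))
  contexts <- as.character(contexts)
  ctxLevels <- unique(contexts)
  nd <- nDraws(draws)
  S <- length(draws@speciesNames)
  cols <- unlist(groups, use.names = FALSE)
  Xg <- Xgrid@X[, cols, drop = FALSE]
  n <- nrow(Xg)

  small <- ctxLevels[table(factor(contexts, ctxLevels))[ctxLevels] < 2]
  if (length(small))
    warning("context(s) with < 2 cells excluded from per-context ",
            "partitions: ", paste(small, collapse = ", "))
  results <- list()
  for (cl in setdiff(ctxLevels, small)) {
    sub <- new("DesignMatrix", X = Xgrid@X[contexts == cl, , drop = FALSE],
               blocks = Xgrid@blocks, stats = Xgrid@stats,
               units = data.frame())
    results[[cl]] <- variancePartition(draws, sub, groups)
  }

  within <- matrix(0, nd, S); between <- matrix(0, nd, S)
  total <- matrix(0, nd, S); reVar <- matrix(0, nd, S)
  grpIdx <- lapply(ctxLevels, function(cl) which(contexts == cl))
  for (d in seq_len(nd)) {
    B <- matrix(draws@B[d, , ], ncol = S)[cols, , drop = FALSE]
    F <- Xg %*% B
    mu <- colMeans(F)
    wv <- numeric(S); bv <- numeric(S)
    for (gi in grpIdx) {
      wC <- length(gi) / n
      Fc <- F[gi, , drop = FALSE]
      muc <- colMeans(Fc)
      vc <- colMeans(Fc^2) - muc^2   # population variance
      wv <- wv + wC * vc
      bv <- bv + wC * (muc - mu)^2
    }
    within[d, ] <- wv
    between[d, ] <- bv
    total[d, ] <- colMeans(F^2) - mu^2
    for (r in names(draws@Lambda)) {
      H <- dim(draws@Lambda[[r]])[2]
      if (H) reVar[d, ] <- reVar[d, ] +
          colSums(matrix(draws@Lambda[[r]][d, , ], H, S)^2)
    }
  }
  colnames(within) <- colnames(between) <- colnames(total) <-
    colnames(reVar) <- draws@speciesNames
  new("ContextPartition", contexts = contexts, results = results,
      within = within, between = between, total = total,
      reVariance = reVar, part = draws@part)
}

#' Conditional variance partitioning by functional trait group
#'
#' Pools the (habitat share, climate share) posterior draws of all member
#' species of each trait group (host-plant groups or wing-span bins) into
#' one joint distribution per group, summarised by marginal quantiles.
#'
#' @param vp a [VariancePartitionResult-class].
#' @param groups named character vector mapping species to group labels
#'   (names = species ids).
#' @return named list per group: `draws` (pooled matrix with columns
#'   `habitat`, `climate`), `quantiles` (2.5/50/97.5% per component),
#'   `species`.
#' @export
conditionalVPFunctional <- function(vp, groups) {
  stopifnot(is(vp, "VariancePartitionResult"))
  spp <- dimnames(vp@shares)[[3]]
  groups <- groups[intersect(names(groups), spp)]
  out <- list()
  for (g in unique(groups)) {
    members <- names(groups)[groups == g]
    if (!length(members)) {
      warning("empty trait group skipped: ", g)
      next
    }
    hab <- as.vector(vp@shares[, "habitat", members])
    cli <- as.vector(vp@shares[, "climate", members])
    drawsMat <- cbind(habitat = hab, climate = cli)
    out[[g]] <- list(
      draws = drawsMat,
      quantiles = apply(drawsMat, 2, quantile,
                        probs = c(0.025, 0.5, 0.975)),
      species = members)
  }
  out
}

#' Count species whose occurrence is habitat-dominated
#'
#' Per posterior draw, the number of species whose habitat share exceeds
#' their climate share, with the posterior median and central 95%
#' interval.
#'
#' @param vp a [VariancePartitionResult-class].
#' @return list: `counts` (per draw), `median`, `ci` (2.5/97.5%).
#' @export
dominantDriverCounts <- function(vp) {
  stopifnot(is(vp, "VariancePartitionResult"))
  counts <- apply(vp@shares[, "habitat", , drop = FALSE] >
                    vp@shares[, "climate", , drop = FALSE], 1, sum)
  list(counts = counts, median = median(counts),
       ci = quantile(counts, c(0.025, 0.975)))
}
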
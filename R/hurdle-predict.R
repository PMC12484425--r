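## Prediction from fitted draws, fit metrics, response-curve screening and
## the site-stratified holdout.

# Random-effect contribution for one draw at prediction units.
# assign: per level, integer index into the fitted level ids (NA = new).
.reContribution <- function(draws, d, assign, reMode, newEtaCache) {
  n <- length(assign[[1]]$idx)
  S <- length(draws@speciesNames)
  RE <- matrix(0, n, S)
  for (r in names(draws@Lambda)) {
    H <- dim(draws@Lambda[[r]])[2]
    if (H == 0) next
    Lam <- matrix(draws@Lambda[[r]][d, , ], H, S)
    a <- assign[[r]]
    eta <- matrix(0, n, H)
    known <- !is.na(a$idx)
    if (any(known))
      eta[known, ] <- matrix(draws@Eta[[r]][d, a$idx[known], ], sum(known), H)
    if (any(!known) && reMode == "sample_new") {
      # one fresh standard-normal score vector per distinct new level unit
      newIds <- unique(a$key[!known])
      etaNew <- matrix(rnorm(length(newIds) * H), length(newIds), H)
      eta[!known, ] <- etaNew[match(a$key[!known], newIds), , drop = FALSE]
    }
    RE <- RE + eta %*% Lam
  }
  RE
}

.matchLevels <- function(draws, units, n) {
  assign <- list()
  for (r in names(draws@Lambda)) {
    key <- if (!is.null(units) && r %in% names(units))
      as.character(units[[r]]) else rep(NA_character_, n)
    assign[[r]] <- list(key = key, idx = match(key, draws@levelIds[[r]]))
  }
  if (!length(assign)) assign <- list(none = list(key = rep(NA, n),
                                                  idx = rep(NA_integer_, n)))
  assign
}

#' Predict occurrence and abundance over new units
#'
#' For each retained draw, computes the linear predictors of both model
#' parts, the occurrence probability `p = Phi(L_PA)`, the conditional
#' abundance mean `m = exp(L_AB + sigma_j^2 / 2)` and the unconditional
#' expected abundance `p * m`. Units whose random-level value was observed
#' in fitting use its posterior factor scores (partial pooling); unobserved
#' level values get zero scores under `reMode = "marginal_zero"` (the
#' posterior-expected surface) or fresh standard-normal scores per draw
#' under `"sample_new"` (a stochastic new-unit realisation).
#'
#' @param paDraws,abDraws [PosteriorDraws-class] for the two parts;
#'   `abDraws` may be `NULL` for occurrence-only prediction.
#' @param Xnew a [DesignMatrix-class] built with the training
#'   standardization statistics.
#' @param units optional data.frame with `site` / `year` / `zone` columns
#'   per prediction row; defaults to `Xnew@units`.
#' @param reMode `"marginal_zero"` or `"sample_new"`.
#' @param drawIndices draws to use (default all).
#' @param summary if `TRUE` return posterior means (matrices units x
#'   species); if `FALSE` return per-draw arrays `[draw, unit, species]`.
#' @return list with elements `p`, `mCond`, `abundance` (and `LPA`,
#'   `LAB` when `summary = FALSE`).
#' @export
predictHurdle <- function(paDraws, abDraws = NULL, Xnew, units = NULL,
                          reMode = c("marginal_zero", "sample_new"),
                          drawIndices = NULL, summary = TRUE) {
  reMode <- match.arg(reMode)
  stopifnot(is(paDraws, "PosteriorDraws"), paDraws@part == "PA")
  X <- Xnew@X
  if (is.null(units)) units <- Xnew@units
  n <- nrow(X); S <- length(paDraws@speciesNames)
  if (is.null(drawIndices)) drawIndices <- seq_len(nDraws(paDraws))
  nd <- length(drawIndices)
  asgPA <- .matchLevels(paDraws, units, n)
  asgAB <- if (!is.null(abDraws)) .matchLevels(abDraws, units, n)
  if (summary) {
    accP <- matrix(0, n, S); accM <- matrix(0, n, S); accU <- matrix(0, n, S)
    accLAB <- matrix(0, n, S)
  } else {
    arrP <- array(NA_real_, c(nd, n, S)); arrM <- array(NA_real_, c(nd, n, S))
    arrLPA <- array(NA_real_, c(nd, n, S)); arrLAB <- array(NA_real_, c(nd, n, S))
  }
  for (k in seq_len(nd)) {
    d <- drawIndices[k]
    LPA <- X %*% matrix(paDraws@B[d, , ], ncol = S) +
      .reContribution(paDraws, d, asgPA, reMode, NULL)
    p <- pnorm(LPA)
    if (!is.null(abDraws)) {
      LAB <- X %*% matrix(abDraws@B[d, , ], ncol = S) +
        .reContribution(abDraws, d, asgAB, reMode, NULL)
      s2 <- abDraws@sigma[d, ]^2
      m <- exp(sweep(LAB, 2, s2 / 2, "+"))
    } else {
      LAB <- matrix(NA_real_, n, S); m <- matrix(NA_real_, n, S)
    }
    if (summary) {
      accP <- accP + p
      if (!is.null(abDraws)) {
        accM <- accM + m; accU <- accU + p * m; accLAB <- accLAB + LAB
      }
    } else {
      arrP[k, , ] <- p; arrM[k, , ] <- m
      arrLPA[k, , ] <- LPA; arrLAB[k, , ] <- LAB
    }
  }
  spn <- paDraws@speciesNames
  if (summary) {
    dimnames(accP) <- list(NULL, spn)
    list(p = accP / nd,
         mCond = if (is.null(abDraws)) NULL else accM / nd,
         abundance = if (is.null(abDraws)) NULL else accU / nd,
         LABmean = if (is.null(abDraws)) NULL else accLAB / nd)
  } else {
    list(p = arrP, mCond = arrM, LPA = arrLPA, LAB = arrLAB)
  }
}

#' Tjur R-squared of occurrence predictions
#'
#' Mean predicted probability over units where the species is present
#' minus the mean over units where it is absent. Undefined (NA) when the
#' truth has a single class.
#'
#' @param p predicted probabilities.
#' @param y binary truth.
#' @return numeric in `[-1, 1]`, or `NA`.
#' @export
tjurR2 <- function(p, y) {
  if (length(unique(y)) < 2) return(NA_real_)
  mean(p[y == 1]) - mean(p[y == 0])
}

#' AUC by Mann-Whitney concordance
#'
#' Probability that a randomly chosen presence outranks a randomly chosen
#' absence, with ties credited 0.5. Undefined (NA) for single-class truth.
#'
#' @inheritParams tjurR2
#' @return numeric in `[0, 1]`, or `NA`.
#' @export
aucMW <- function(p, y) {
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(p)                      # average ranks = 0.5 credit for ties
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate hurdle-model predictions against a community
#'
#' Per-species Tjur R-squared and AUC for occurrence and squared Pearson
#' correlation of observed vs predicted log counts on positive units for
#' abundance; plus their cross-species means.
#'
#' @param pred result of [predictHurdle()] with `summary = TRUE`.
#' @param community a [CommunityTable-class] over the same units (rows of
#'   the prediction matrices = columns of the community).
#' @return list with `perSpecies` (data.frame) and `summary` (named
#'   means).
#' @export
evaluateHurdle <- function(pred, community) {
  cnt <- t(assay(community, "counts"))   # units x species
  pa <- (cnt > 0) * 1
  spp <- colnames(pred$p)
  cnt <- cnt[, spp, drop = FALSE]; pa <- pa[, spp, drop = FALSE]
  perSp <- data.frame(species = spp,
                      tjur_r2 = NA_real_, auc = NA_real_, r2_log = NA_real_)
  for (j in seq_along(spp)) {
    perSp$tjur_r2[j] <- tjurR2(pred$p[, j], pa[, j])
    perSp$auc[j] <- aucMW(pred$p[, j], pa[, j])
    pos <- cnt[, j] > 0
    if (!is.null(pred$LABmean) && sum(pos) >= 3 &&
        sd(pred$LABmean[pos, j]) > 0 && sd(log(cnt[pos, j])) > 0)
      perSp$r2_log[j] <- cor(log(cnt[pos, j]), pred$LABmean[pos, j])^2
  }
  list(perSpecies = perSp,
       summary = c(tjur_r2 = mean(perSp$tjur_r2, na.rm = TRUE),
                   auc = mean(perSp$auc, na.rm = TRUE),
                   r2_log = mean(perSp$r2_log, na.rm = TRUE)))
}

#' Screen environmental response curves
#'
#' Evaluates the posterior-mean linear predictor of each species along one
#' covariate (its linear and, where present, quadratic term), holding all
#' other columns at their design means, and labels the shape: `U-shaped`
#' iff the posterior-mean quadratic coefficient is positive and the
#' interior minimum falls inside the covariate's observed range;
#' `unimodal` iff the quadratic coefficient is negative with the peak
#' inside the range; otherwise `monotone`. Covariates modelled without a
#' quadratic term (clumpiness, entropy, effort) are always `monotone`.
#'
#' @param draws a [PosteriorDraws-class].
#' @param design the training [DesignMatrix-class].
#' @param covariate linear-column name, e.g. `"clim_gdd"`.
#' @param n grid resolution along the covariate.
#' @return list: `values` (grid), `curves` (grid x species matrix),
#'   `shape` (per-species label).
#' @export
responseCurves <- function(draws, design, covariate, n = 50) {
  X <- design@X
  if (!covariate %in% colnames(X)) stop("unknown covariate: ", covariate)
  Bbar <- posteriorMean(draws, "B")
  dimnames(Bbar) <- list(draws@covNames, draws@speciesNames)
  sqName <- paste0(covariate, "_sq")
  hasQuad <- sqName %in% colnames(X)
  rng <- range(X[, covariate])
  v <- seq(rng[1], rng[2], length.out = n)
  xbar <- colMeans(X)
  base <- as.vector(xbar %*% Bbar) -
    xbar[covariate] * Bbar[covariate, ] -
    (if (hasQuad) xbar[sqName] * Bbar[sqName, ] else 0)
  curves <- outer(v, Bbar[covariate, ]) +
    (if (hasQuad) outer(v^2, Bbar[sqName, ]) else 0)
  curves <- sweep(curves, 2, base, "+")
  shape <- rep("monotone", ncol(Bbar))
  if (hasQuad) {
    bq <- Bbar[sqName, ]; bl <- Bbar[covariate, ]
    vertex <- ifelse(bq != 0, -bl / (2 * bq), NA_real_)
    inside <- !is.na(vertex) & vertex > rng[1] & vertex < rng[2]
    shape[bq > 0 & inside] <- "U-shaped"
    shape[bq < 0 & inside] <- "unimodal"
  }
  names(shape) <- colnames(Bbar)
  list(values = v, curves = curves, shape = shape)
}

#' Site-stratified holdout validation
#'
#' Splits sites (not trap-years) into training and holdout sets, fits both
#' hurdle parts on the training units, and evaluates explanatory metrics
#' on the training units and predictive metrics on the holdout units
#' (holdout sites use zero site factor scores; observed year and zone
#' levels use their posterior scores). `holdoutFrac = 0` fits on all units
#' and reports identical explanatory and predictive metrics.
#'
#' @param community a [CommunityTable-class].
#' @param covariates raw covariate table aligned with the community units
#'   (see [buildDesignMatrix()]).
#' @param traits trait table or `NULL`.
#' @param spec a [hurdleModelSpec()].
#' @param splitSeed seed of the site split.
#' @param holdoutFrac fraction of sites held out.
#' @return list: `explanatory`, `predictive` (each an [evaluateHurdle()]
#'   result), `holdoutSites`.
#' @export
holdoutValidate <- function(community, covariates, traits = NULL,
                            spec = hurdleModelSpec(), splitSeed = 1,
                            holdoutFrac = 0.2) {
  stopifnot(holdoutFrac >= 0, holdoutFrac < 1)
  cd <- as.data.frame(colData(community))
  sites <- unique(cd$site)
  set.seed(as.integer(splitSeed))
  nHold <- floor(holdoutFrac * length(sites))
  holdSites <- if (nHold > 0) sample(sites, nHold) else character(0)
  holdIdx <- cd$site %in% holdSites
  trainCT <- community[, !holdIdx]
  trainCov <- covariates[!holdIdx, , drop = FALSE]
  design <- buildDesignMatrix(trainCov)
  pa <- fitPA(trainCT, design, traits, spec)
  ab <- fitAB(trainCT, design, traits, spec)
  evalOn <- function(idx) {
    Xe <- buildDesignMatrix(covariates[idx, , drop = FALSE],
                            stats = design@stats)
    pr <- predictHurdle(pa, ab, Xe, units = cd[idx, , drop = FALSE])
    evaluateHurdle(pr, community[, idx])
  }
  expl <- evalOn(!holdIdx)
  predv <- if (any(holdIdx)) evalOn(holdIdx) else expl
  list(explanatory = expl, predictive = predv, holdoutSites = holdSites)
}
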
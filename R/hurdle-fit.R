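## User-facing fitting interface for the two hurdle parts.

#' Specify priors and MCMC settings for the hurdle JSDM
#'
#' Defaults are weakly informative. The latent-factor prior uses a fixed
#' small factor count per random level with a geometric variance decay
#' (the prior variance of the loadings halves with each successive
#' factor), which keeps the per-species random-effect variance
#' `sum_h lambda_h^2` interpretable while keeping all full conditionals
#' conjugate.
#'
#' @param nFactors named integer vector of latent factors per random level
#'   (default `c(site = 2, year = 1, zone = 1)`); a level with 0 factors
#'   is dropped from the model.
#' @param gammaVar prior variance of each trait-effect entry.
#' @param omegaNuExtra Inverse-Wishart degrees of freedom in excess of the
#'   number of covariates (`nu = K + omegaNuExtra`; must be `> 1` so the
#'   prior mean exists).
#' @param omegaPsiScale diagonal of the Inverse-Wishart scale matrix.
#' @param lambdaVar prior variance of first-factor loadings; halves per
#'   successive factor.
#' @param sigmaA,sigmaB Inverse-Gamma shape and rate for the abundance
#'   residual variances.
#' @param chains,iterations,burnin,thin MCMC settings; `burnin` is a
#'   fraction of `iterations`, retained draw count is
#'   `chains * (iterations - burnin * iterations) / thin`.
#' @param seed integer MCMC seed (each chain derives its own).
#' @param fixedGamma,fixedOmega optional fixed values (matrices); when
#'   supplied the corresponding Gibbs update is skipped. Used for
#'   conjugate debug checks.
#' @param gaussianDebug logical; when `TRUE`, [fitPA()] treats the
#'   response as directly observed Gaussian latents (no probit
#'   truncation), which makes the sampler's target the closed-form
#'   Bayesian linear regression posterior.
#' @return list of class `hurdleModelSpec`.
#' @export
hurdleModelSpec <- function(nFactors = c(site = 2L, year = 1L, zone = 1L),
                            gammaVar = 4, omegaNuExtra = 2,
                            omegaPsiScale = 0.5, lambdaVar = 1,
                            sigmaA = 2, sigmaB = 1,
                            chains = 2L, iterations = 2000L, burnin = 0.5,
                            thin = 2L, seed = 1L,
                            fixedGamma = NULL, fixedOmega = NULL,
                            gaussianDebug = FALSE) {
  stopifnot(omegaNuExtra > 1, gammaVar > 0, omegaPsiScale > 0,
            lambdaVar > 0, sigmaA > 0, sigmaB > 0,
            chains >= 1, iterations >= 2, burnin >= 0, burnin < 1,
            thin >= 1, all(nFactors >= 0))
  spec <- list(nFactors = nFactors, gammaVar = gammaVar,
               omegaNuExtra = omegaNuExtra, omegaPsiScale = omegaPsiScale,
               lambdaVar = lambdaVar, sigmaA = sigmaA, sigmaB = sigmaB,
               chains = as.integer(chains),
               iterations = as.integer(iterations), burnin = burnin,
               thin = as.integer(thin), seed = as.integer(seed),
               fixedGamma = fixedGamma, fixedOmega = fixedOmega,
               gaussianDebug = gaussianDebug)
  class(spec) <- "hurdleModelSpec"
  spec
}

# Shared front end of fitPA/fitAB: dims, trait matrix, level factors.
.prepareFit <- function(Y, design, traits, spec, units) {
  X <- design@X
  stopifnot(nrow(Y) == nrow(X))
  S <- ncol(Y)
  Tm <- if (is.null(traits)) matrix(1, S, 1,
                                    dimnames = list(colnames(Y), "intercept"))
        else encodeTraits(traits)
  if (nrow(Tm) != S) stop("trait table must have one row per species")
  if (is.null(units)) units <- design@units
  levelAssign <- list()
  for (r in names(spec$nFactors)) {
    if (spec$nFactors[[r]] == 0) next
    if (!r %in% names(units))
      stop("random level '", r, "' not found among unit columns")
    levelAssign[[r]] <- droplevels(factor(units[[r]]))
  }
  list(X = X, Tm = Tm, levelAssign = levelAssign)
}

.runChains <- function(Y, X, mask, Tm, levelAssign, spec, part) {
  chains <- lapply(seq_len(spec$chains), function(ch)
    .gibbsChain(Y, X, mask, Tm, levelAssign, spec, part,
                chainSeed = spec$seed + 1000L * (ch - 1L)))
  combine <- function(get) {
    arrs <- lapply(chains, get)
    ab <- do.call(abind1, arrs)
    ab
  }
  nKeep <- dim(chains[[1]]$B)[1]
  out <- list(
    B = combine(function(c) c$B),
    Gamma = combine(function(c) c$Gamma),
    Omega = combine(function(c) c$Omega),
    sigma = do.call(rbind, lapply(chains, function(c) c$sigma)),
    Lambda = lapply(names(levelAssign), function(r)
      combine(function(c) c$Lambda[[r]])),
    Eta = lapply(names(levelAssign), function(r)
      combine(function(c) c$Eta[[r]])),
    clipped = sum(vapply(chains, function(c) c$clipped, numeric(1))),
    rhat = tryCatch(.splitRhat(lapply(chains, function(c) c$B)),
                    error = function(e) NA_real_)
  )
  names(out$Lambda) <- names(levelAssign)
  names(out$Eta) <- names(levelAssign)
  out
}

# rbind along the first margin of equal-shaped arrays
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n1 <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, c(n1, d[-1]))
  at <- 0L
  for (a in arrs) {
    idx <- at + seq_len(dim(a)[1])
    if (length(d) == 3) out[idx, , ] <- a else out[idx, ] <- a
    at <- at + dim(a)[1]
  }
  out
}

.makeDraws <- function(res, part, design, levelAssign, spec) {
  new("PosteriorDraws",
      part = part,
      B = res$B, Gamma = res$Gamma, Omega = res$Omega,
      Lambda = res$Lambda, Eta = res$Eta,
      sigma = if (part == "AB") res$sigma else
        matrix(numeric(0), dim(res$B)[1], 0),
      covNames = colnames(design@X),
      speciesNames = res$speciesNames,
      blocks = design@blocks,
      levelIds = lapply(levelAssign, levels),
      nChains = spec$chains,
      diagnostics = list(clippedZ = res$clipped, rhat = res$rhat))
}

#' Fit the presence-absence (probit) part of the hurdle JSDM
#'
#' Gibbs sampler cycling truncated-normal latent draws (probit data
#' augmentation), conjugate normal updates of the species coefficients,
#' conjugate normal / Inverse-Wishart updates of the trait effects and
#' coefficient covariance, and normal updates of the latent factor scores
#' and loadings per random level. The probit residual variance is fixed at
#' 1 for identifiability. Latents beyond +-40 are clipped and counted in
#' the diagnostics.
#'
#' @param Y binary units x species matrix (or a [CommunityTable-class],
#'   whose presence-absence view is used with units as rows).
#' @param design a [DesignMatrix-class] over the same units.
#' @param traits species trait data.frame (see [encodeTraits()]) or `NULL`
#'   for a trait-free fit (intercept-only trait matrix).
#' @param spec a [hurdleModelSpec()].
#' @param units optional data.frame with the random-level columns
#'   (`site`, `year`, `zone`) per unit; defaults to the design's unit
#'   table.
#' @return a [PosteriorDraws-class] with `part = "PA"`.
#' @export
fitPA <- function(Y, design, traits = NULL, spec = hurdleModelSpec(),
                  units = NULL) {
  if (is(Y, "CommunityTable")) {
    if (is.null(units)) units <- as.data.frame(colData(Y))
    Y <- t(presenceAbsence(Y)) * 1
  }
  Y <- as.matrix(Y)
  if (!all(Y %in% c(0, 1)) && !isTRUE(spec$gaussianDebug))
    stop("Y must be binary for the probit part")
  if (anyNA(Y)) stop("missing cells are not allowed")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sp", seq_len(ncol(Y)))
  pf <- .prepareFit(Y, design, traits, spec, units)
  mask <- matrix(TRUE, nrow(Y), ncol(Y))
  res <- .runChains(Y, pf$X, mask, pf$Tm, pf$levelAssign, spec, "PA")
  res$speciesNames <- colnames(Y)
  .makeDraws(res, "PA", design, pf$levelAssign, spec)
}

#' Fit the abundance-conditional-on-presence (lognormal) part
#'
#' Same sampler as [fitPA()] with a Gaussian response `log(count)`
#' restricted to units where the species is present; units where a
#' species is absent contribute nothing to that species' likelihood.
#' Residual variances are sampled from their Inverse-Gamma full
#' conditional.
#'
#' @param Y counts units x species matrix (or a [CommunityTable-class]).
#' @inheritParams fitPA
#' @return a [PosteriorDraws-class] with `part = "AB"`.
#' @export
fitAB <- function(Y, design, traits = NULL, spec = hurdleModelSpec(),
                  units = NULL) {
  if (is(Y, "CommunityTable")) {
    if (is.null(units)) units <- as.data.frame(colData(Y))
    Y <- t(assay(Y, "counts"))
  }
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("counts must be non-negative")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sp", seq_len(ncol(Y)))
  mask <- Y > 0
  few <- colSums(mask) < 5
  if (any(few))
    warning("species with < 5 positive units: ",
            paste(colnames(Y)[few], collapse = ", "),
            " (expect wide posteriors)")
  if (any(colSums(mask) == 0))
    stop("species with no positive units cannot enter the abundance part")
  Z <- ifelse(mask, log(pmax(Y, 1)), 0)
  pf <- .prepareFit(Z, design, traits, spec, units)
  res <- .runChains(Z, pf$X, mask, pf$Tm, pf$levelAssign, spec, "AB")
  res$speciesNames <- colnames(Y)
  .makeDraws(res, "AB", design, pf$levelAssign, spec)
}
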
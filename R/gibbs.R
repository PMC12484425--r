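## Gibbs sampler for the multivariate probit / Gaussian JSDM with
## trait-structured coefficient priors and latent-factor random effects.
##
## Model, per unit i and species j:
##   z_ij = x_i' B_j + sum_r eta_{r, l_r(i)}' lambda_{r, j} + eps_ij
## PA part: eps ~ N(0, 1), y = 1(z > 0) (probit data augmentation).
## AB part: z = log(count) observed on units where the species is present,
##          eps ~ N(0, sigma_j^2).
## Priors: B_j ~ N(Gamma t_j, Omega); rows of Gamma ~ N(0, tauGamma^2);
## Omega ~ InvWishart(nu, Psi); lambda_{r,h,j} ~ N(0, tauLambda^2 2^-(h-1));
## eta ~ N(0, 1); sigma_j^2 ~ InvGamma(a, b).

# Truncated-normal draw via inverse CDF, vectorized. lower/upper are
# -Inf/0 or 0/Inf here, so plain pnorm/qnorm precision suffices; extreme
# latents are clipped at +-40 and counted.
.rtruncnorm <- function(mu, lower, upper) {
  pl <- pnorm(lower - mu)
  pu <- pnorm(upper - mu)
  u <- runif(length(mu), pl, pu)
  z <- mu + qnorm(u)
  # tail fallback: if the interval mass underflows, pin to the near bound
  bad <- !is.finite(z)
  if (any(bad)) z[bad] <- ifelse(is.finite(lower[bad]), lower[bad], upper[bad])
  z
}

# Draw from N(Prec^-1 rhs, Prec^-1) given the precision matrix.
.rmvnormPrec <- function(Prec, rhs) {
  U <- chol(Prec)
  mu <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
  mu + backsolve(U, rnorm(nrow(Prec)))
}

# One chain of the sampler. Returns a list of draw arrays.
.gibbsChain <- function(Y, X, mask, Tm, levelAssign, spec, part, chainSeed) {
  set.seed(chainSeed)
  n <- nrow(X); K <- ncol(X); S <- ncol(Y); Tt <- ncol(Tm)
  levNames <- names(levelAssign)
  nFac <- spec$nFactors[levNames]
  nLev <- vapply(levelAssign, nlevels, integer(1))
  gaussian <- part == "AB" || isTRUE(spec$gaussianDebug)

  maskN <- colSums(mask)                 # observed units per species
  idxS <- lapply(seq_len(S), function(j) which(mask[, j]))
  XtXs <- if (part == "AB")
    lapply(idxS, function(ix) crossprod(X[ix, , drop = FALSE])) else NULL
  XtX <- crossprod(X)
  # per-level bookkeeping: unit index per level unit, obs counts per
  # (level unit, species)
  levIdx <- lapply(levelAssign, function(f) as.integer(f))
  # integer grouping keeps rowsum rows aligned with factor-level order
  nObsLS <- lapply(levIdx, function(ix) rowsum((mask) * 1, ix, reorder = TRUE))

  # prior settings
  tauG2 <- spec$gammaVar
  nu <- K + spec$omegaNuExtra
  Psi <- diag(spec$omegaPsiScale, K)
  tauL2 <- lapply(nFac, function(H)
    if (H > 0) spec$lambdaVar * 2^(-(seq_len(H) - 1)) else numeric(0))
  aSig <- spec$sigmaA; bSig <- spec$sigmaB

  fixedGamma <- spec$fixedGamma
  fixedOmega <- spec$fixedOmega

  # state
  Gamma <- if (is.null(fixedGamma)) matrix(0, K, Tt) else fixedGamma
  Omega <- if (is.null(fixedOmega)) diag(1, K) else fixedOmega
  OmegaInv <- chol2inv(chol(Omega))
  B <- matrix(0, K, S)
  sigma2 <- rep(1, S)
  Lambda <- lapply(levNames, function(r)
    matrix(0, nFac[[r]], S))
  names(Lambda) <- levNames
  Eta <- lapply(levNames, function(r) matrix(0, nLev[[r]], nFac[[r]]))
  names(Eta) <- levNames
  RE <- matrix(0, n, S)
  reOf <- function(r) {
    if (nFac[[r]] == 0) return(matrix(0, n, S))
    Eta[[r]][levIdx[[r]], , drop = FALSE] %*% Lambda[[r]]
  }
  z <- if (gaussian) Y else ifelse(Y > 0, 0.7, -0.7)
  z[!mask] <- 0
  clipped <- 0L

  nIter <- spec$iterations
  burn <- floor(spec$burnin * nIter)
  keepIdx <- seq(burn + 1L, nIter, by = spec$thin)
  nKeep <- length(keepIdx)
  out <- list(
    B = array(NA_real_, c(nKeep, K, S)),
    Gamma = array(NA_real_, c(nKeep, K, Tt)),
    Omega = array(NA_real_, c(nKeep, K, K)),
    Lambda = lapply(levNames, function(r) array(NA_real_, c(nKeep, nFac[[r]], S))),
    Eta = lapply(levNames, function(r) array(NA_real_, c(nKeep, nLev[[r]], nFac[[r]]))),
    sigma = matrix(NA_real_, nKeep, S)
  )
  names(out$Lambda) <- levNames; names(out$Eta) <- levNames
  keepPtr <- 0L

  for (it in seq_len(nIter)) {
    ## 1. latent z (probit part only)
    if (!gaussian) {
      Mu <- X %*% B + RE
      lower <- ifelse(Y > 0, 0, -Inf)
      upper <- ifelse(Y > 0, Inf, 0)
      z <- matrix(.rtruncnorm(as.vector(Mu), as.vector(lower),
                              as.vector(upper)), n, S)
      over <- abs(z) > 40
      if (any(over)) {
        clipped <- clipped + sum(over)
        z[over] <- sign(z[over]) * 40
      }
    }

    ## 2. species coefficients B
    R <- z - RE
    Mu0 <- Gamma %*% t(Tm)               # K x S prior means
    if (part == "PA") {
      U <- chol(XtX + OmegaInv)
      XtR <- crossprod(X, R)
      rhs <- XtR + OmegaInv %*% Mu0
      Bmean <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
      B <- Bmean + backsolve(U, matrix(rnorm(K * S), K, S))
    } else {
      for (j in seq_len(S)) {
        ix <- idxS[[j]]
        Prec <- XtXs[[j]] / sigma2[j] + OmegaInv
        rhs <- crossprod(X[ix, , drop = FALSE], R[ix, j]) / sigma2[j] +
          OmegaInv %*% Mu0[, j]
        B[, j] <- .rmvnormPrec(Prec, rhs)
      }
    }

    ## 3. trait effects Gamma and coefficient covariance Omega
    if (is.null(fixedGamma)) {
      TtT <- crossprod(Tm)
      Prec <- kronecker(TtT, OmegaInv) + diag(1 / tauG2, K * Tt)
      rhs <- as.vector(OmegaInv %*% B %*% Tm)
      Gamma <- matrix(.rmvnormPrec(Prec, rhs), K, Tt)
    }
    if (is.null(fixedOmega)) {
      E <- B - Gamma %*% t(Tm)
      Sc <- Psi + tcrossprod(E)
      OmegaInv <- matrix(rWishart(1, nu + S, chol2inv(chol(Sc)))[, , 1], K, K)
      Omega <- chol2inv(chol(OmegaInv))
    }

    ## 4. latent factors per random level
    XB <- X %*% B
    for (r in levNames) {
      if (nFac[[r]] == 0) next
      REother <- RE - reOf(r)
      resid <- (z - XB - REother)
      resid[!mask] <- 0
      s <- rowsum(resid, levIdx[[r]], reorder = TRUE)  # L x S
      L <- Lambda[[r]]                    # H x S
      H <- nFac[[r]]
      for (l in seq_len(nLev[[r]])) {
        w <- nObsLS[[r]][l, ] / sigma2
        Prec <- diag(1, H) + L %*% (w * t(L))
        rhs <- L %*% (s[l, ] / sigma2)
        Eta[[r]][l, ] <- .rmvnormPrec(Prec, rhs)
      }
      En <- Eta[[r]][levIdx[[r]], , drop = FALSE]  # n x H
      for (j in seq_len(S)) {
        ix <- idxS[[j]]
        Ej <- En[ix, , drop = FALSE]
        Prec <- diag(1 / tauL2[[r]], H) + crossprod(Ej) / sigma2[j]
        rhs <- crossprod(Ej, (z[ix, j] - XB[ix, j] - REother[ix, j])) /
          sigma2[j]
        Lambda[[r]][, j] <- .rmvnormPrec(Prec, rhs)
      }
      RE <- REother + reOf(r)
    }

    ## 5. abundance residual variances
    if (part == "AB") {
      resid <- z - XB - RE
      for (j in seq_len(S)) {
        ss <- sum(resid[idxS[[j]], j]^2)
        sigma2[j] <- 1 / rgamma(1, aSig + maskN[j] / 2, rate = bSig + ss / 2)
      }
    }

    if (it %in% keepIdx) {
      keepPtr <- keepPtr + 1L
      out$B[keepPtr, , ] <- B
      out$Gamma[keepPtr, , ] <- Gamma
      out$Omega[keepPtr, , ] <- Omega
      for (r in levNames) {
        if (nFac[[r]] > 0) {
          out$Lambda[[r]][keepPtr, , ] <- Lambda[[r]]
          out$Eta[[r]][keepPtr, , ] <- Eta[[r]]
        }
      }
      out$sigma[keepPtr, ] <- sqrt(sigma2)
    }
  }
  out$clipped <- clipped
  out
}

# Split-Rhat over a sample of B entries, computed chain-wise on the
# retained draws (each chain's draws split in half).
.splitRhat <- function(Blist) {
  entries <- dim(Blist[[1]])[2] * dim(Blist[[1]])[3]
  pick <- sample(entries, max(1, ceiling(0.05 * entries)))
  rhat1 <- function(chains) {
    m <- length(chains); nn <- length(chains[[1]])
    mu <- vapply(chains, mean, numeric(1))
    W <- mean(vapply(chains, var, numeric(1)))
    Bv <- nn * var(mu)
    sqrt(((nn - 1) / nn * W + Bv / nn) / W)
  }
  vapply(pick, function(e) {
    halves <- unlist(lapply(Blist, function(Bc) {
      flat <- matrix(Bc, nrow = dim(Bc)[1])[, e]
      half <- floor(length(flat) / 2)
      list(flat[seq_len(half)], flat[seq(half + 1, 2 * half)])
    }), recursive = FALSE)
    rhat1(halves)
  }, numeric(1))
}
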
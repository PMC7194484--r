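## Trivariate Cholesky AE model: three phenotypes per twin, additive-genetic
## and nonshared-environment factors each with a lower-triangular path
## structure. Cross-twin genetic covariance is scaled 1 (MZ) / 0.5 (DZ).

## multivariate-normal log density for rows of X (allowing a missing-data
## pattern handled by the caller through column subsetting)
.mvnLoglik <- function(X, mu, Sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Z <- backsolve(ch, t(X) - mu, transpose = TRUE)
  quad <- colSums(Z^2)
  sum(-0.5 * (p * log(2 * pi) + logdet + quad))
}

.pairCov <- function(A, E, k) {
  S <- A %*% t(A) + E %*% t(E)
  C <- k * (A %*% t(A))
  rbind(cbind(S, C), cbind(C, S))
}

#' Fit a trivariate AE Cholesky twin model
#'
#' Maximum-likelihood fit of a three-phenotype AE Cholesky decomposition to
#' twin-pair data: each twin's 3-vector loads on three additive-genetic (A)
#' and three nonshared-environment (E) factors through lower-triangular
#' path matrices; the cross-twin A covariance is the full genetic
#' covariance for MZ pairs and half of it for DZ pairs. Pairs with partly
#' missing phenotypes contribute their observed block (full-information
#' likelihood). Phenotypes are standardized internally, so the reported
#' paths are unsquared standardized path estimates (for each trait the
#' squared A and E paths sum to one); their standard errors come from the
#' observed information matrix by the delta method. Factor sign is
#' normalized so diagonal paths are non-negative.
#'
#' @param pairs a [TwinPairTable-class] carrying the three phenotypes.
#' @param traits character(3) phenotype names, in model order.
#' @return A [CholeskyFit-class].
#' @export
fitCholeskyTrivariate <- function(pairs,
                                  traits = phenotypes(pairs)[1:3]) {
  stopifnot(length(traits) == 3L, all(traits %in% phenotypes(pairs)))
  p <- pairData(pairs)
  Y <- as.matrix(p[, c(paste0(traits, "_1"), paste0(traits, "_2"))])
  ## standardize each trait using all twins pooled
  for (j in 1:3) {
    vals <- c(Y[, j], Y[, j + 3])
    m <- mean(vals, na.rm = TRUE); s <- sd(vals, na.rm = TRUE)
    Y[, j] <- (Y[, j] - m) / s
    Y[, j + 3] <- (Y[, j + 3] - m) / s
  }
  zyg <- p$zygosity
  keep <- rowSums(is.finite(Y)) > 0
  Y <- Y[keep, , drop = FALSE]; zyg <- zyg[keep]
  nMZ <- sum(zyg == "MZ"); nDZ <- sum(zyg == "DZ")
  if (nMZ < 30 || nDZ < 30)
    stop("need at least 30 pairs per zygosity with trivariate data")

  ## group pairs by (zygosity, missingness pattern) for fast likelihood
  pat <- apply(is.finite(Y), 1, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(nrow(Y)), paste(zyg, pat))

  lowerIdx <- which(lower.tri(diag(3), diag = TRUE))
  unpack <- function(th) {
    mu <- th[1:3]
    A <- matrix(0, 3, 3); A[lowerIdx] <- th[4:9]
    E <- matrix(0, 3, 3); E[lowerIdx] <- th[10:15]
    list(mu = mu, A = A, E = E)
  }
  nll <- function(th) {
    par <- unpack(th)
    if (any(abs(diag(par$E)) < 1e-8)) return(1e10)
    ll <- 0
    for (g in names(groups)) {
      idx <- groups[[g]]
      zg <- zyg[idx[1]]
      obs <- which(is.finite(Y[idx[1], ]))
      Sig <- .pairCov(par$A, par$E, if (zg == "MZ") 1 else 0.5)
      mu6 <- rep(par$mu, 2)
      llg <- .mvnLoglik(Y[idx, obs, drop = FALSE], mu6[obs],
                        Sig[obs, obs, drop = FALSE])
      if (!is.finite(llg)) return(1e10)
      ll <- ll + llg
    }
    -ll
  }
  th0 <- c(rep(0, 3), 0.5, 0.1, 0.1, 0.5, 0.1, 0.1,
           0.8, 0.1, 0.1, 0.8, 0.1, 0.8)
  fit <- optim(th0, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-10))
  fit2 <- optim(fit$par, nll, method = "BFGS",
                control = list(maxit = 2000, reltol = 1e-12))
  if (fit2$value < fit$value) fit <- fit2

  ## standardized paths and delta-method SEs
  stdPaths <- function(th) {
    par <- unpack(th)
    A <- par$A; E <- par$E
    ## sign normalization: diagonal >= 0 (flip factor columns)
    for (k in 1:3) {
      if (A[k, k] < 0) A[, k] <- -A[, k]
      if (E[k, k] < 0) E[, k] <- -E[, k]
    }
    tot <- sqrt(rowSums(A^2) + rowSums(E^2))
    As <- A / tot; Es <- E / tot
    c(As[lowerIdx], Es[lowerIdx])
  }
  est <- stdPaths(fit$par)
  H <- tryCatch(pracma::hessian(nll, fit$par), error = function(e) NULL)
  ses <- rep(NA_real_, 12L)
  if (!is.null(H)) {
    Vp <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vp)) {
      J <- pracma::jacobian(stdPaths, fit$par)
      Vs <- J %*% Vp %*% t(J)
      dg <- diag(Vs)
      dg[dg < 0] <- NA_real_
      ses <- sqrt(dg)
    }
  }
  mk <- function(v) { M <- matrix(0, 3, 3); M[lowerIdx] <- v
                      dimnames(M) <- list(traits, paste0("F", 1:3)); M }
  new("CholeskyFit",
      traits = traits,
      pathsA = mk(est[1:6]), pathsE = mk(est[7:12]),
      seA = mk(ses[1:6]), seE = mk(ses[7:12]),
      loglik = -fit$value, nMZ = nMZ, nDZ = nDZ,
      convergence = fit$convergence)
}
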
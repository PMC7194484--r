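# Independent oracles and fixture builders used across the suite.

# Brute-force bivariate-normal log-likelihood via the conditional-normal
# factorisation f(x1) f(x2 | x1) - deliberately a different route than the
# package's joint quadratic form.
oracleBvnLoglik <- function(x1, x2, m, v, r) {
  s <- sqrt(v)
  ll <- 0
  for (i in seq_along(x1)) {
    condMean <- m + r * (x1[i] - m)
    condVar <- v * (1 - r^2)
    ll <- ll + dnorm(x1[i], m, s, log = TRUE) +
      dnorm(x2[i], condMean, sqrt(condVar), log = TRUE)
  }
  ll
}

oracleTwinLoglik <- function(mz, dz, m, v, a2, c2) {
  oracleBvnLoglik(mz[, 1], mz[, 2], m, v, a2 + c2) +
    oracleBvnLoglik(dz[, 1], dz[, 2], m, v, 0.5 * a2 + c2)
}

# Textbook Welch statistic with Satterthwaite degrees of freedom.
oracleWelch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}

# Minimal TrialEpochSet built directly from a difference matrix, for
# testing the LI computations in isolation from the signal pipeline.
makeEpochSet <- function(diffMat, relT, accepted = rep(TRUE, nrow(diffMat))) {
  L <- diffMat
  R <- matrix(0, nrow(diffMat), ncol(diffMat))
  rd <- S4Vectors::DataFrame(
    trialIndex = seq_len(nrow(diffMat)),
    markerTime = seq_len(nrow(diffMat)) * 100,
    accepted = accepted,
    rejectionReason = ifelse(accepted, "none", "behaviour"),
    baselineLeft = rep(100, nrow(diffMat)),
    baselineRight = rep(100, nrow(diffMat)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(left = L, right = R, diff = L - R),
    rowData = rd,
    colData = S4Vectors::DataFrame(relTime = relT),
    metadata = list(subjectId = "fixture"))
  new("TrialEpochSet", se)
}

# Twin table built from explicit per-pair values.
makePairs <- function(mz1, mz2, dz1, dz2, pheno = "y") {
  n <- length(mz1) + length(dz1)
  d <- data.frame(
    familyId = sprintf("f%03d", seq_len(n)),
    zygosity = rep(c("MZ", "DZ"), c(length(mz1), length(dz1))),
    stringsAsFactors = FALSE)
  d[[paste0(pheno, "_1")]] <- c(mz1, dz1)
  d[[paste0(pheno, "_2")]] <- c(mz2, dz2)
  TwinPairTable(d, phenotypes = pheno)
}

# Trial-level cohort generator with a closed-form split-half reliability:
# subject truth ~ N(mu, sdSubject), trial noise ~ N(0, sdNoise). The
# expected odd-even correlation is
#   sdSubject^2 / (sdSubject^2 + 2 sdNoise^2 / nTrials).
simulateTrialLICohort <- function(nSubjects, nTrials, mu = 2,
                                  sdSubject = 1.5, sdNoise = 4, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nSubjects), function(i) {
    truth <- rnorm(1, mu, sdSubject)
    data.frame(subjectId = sprintf("s%04d", i),
               trialLIMean = truth + rnorm(nTrials, 0, sdNoise))
  })
  do.call(rbind, rows)
}

# Trivariate twin generator with known lower-triangular standardized A
# paths; E paths fill each trait's variance to 1.
simulateTrivariate <- function(nMZ, nDZ, A, seed = 1) {
  set.seed(seed)
  E <- t(chol(diag(3) - A %*% t(A)))
  n <- nMZ + nDZ
  zyg <- rep(c("MZ", "DZ"), c(nMZ, nDZ))
  wShared <- ifelse(zyg == "MZ", 1, sqrt(0.5))
  wOwn <- ifelse(zyg == "MZ", 0, sqrt(0.5))
  shared <- matrix(rnorm(3 * n), n)
  A1 <- shared * wShared + matrix(rnorm(3 * n), n) * wOwn
  A2 <- shared * wShared + matrix(rnorm(3 * n), n) * wOwn
  y1 <- A1 %*% t(A) + matrix(rnorm(3 * n), n) %*% t(E)
  y2 <- A2 %*% t(A) + matrix(rnorm(3 * n), n) %*% t(E)
  d <- data.frame(familyId = sprintf("f%05d", seq_len(n)), zygosity = zyg,
                  ehi_1 = y1[, 1], qhp_1 = y1[, 2], li_1 = y1[, 3],
                  ehi_2 = y2[, 1], qhp_2 = y2[, 2], li_2 = y2[, 3],
                  stringsAsFactors = FALSE)
  TwinPairTable(d, phenotypes = c("ehi", "qhp", "li"))
}
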
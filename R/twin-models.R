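## Maximum-likelihood twin variance decomposition (ACE family), twin-cotwin
## correlations, Falconer moment estimates, nested-model comparison and
## profile-likelihood intervals.
##
## The phenotypic model: for a pair with values (x1, x2), mean m and total
## variance v, the pair vector is bivariate normal with correlation
## r = a2 + c2 (MZ) or 0.5 a2 + c2 (DZ), where a2, c2, e2 are the
## standardized additive-genetic, shared-environment and nonshared
## environment proportions (a2 + c2 + e2 = 1).

## sum of bivariate-normal log densities for pairs with common mean/variance
.bvnLoglik <- function(x1, x2, m, v, r) {
  if (v <= 0 || abs(r) >= 1) return(-Inf)
  z1 <- (x1 - m) / sqrt(v)
  z2 <- (x2 - m) / sqrt(v)
  q <- (z1^2 - 2 * r * z1 * z2 + z2^2) / (1 - r^2)
  sum(-log(2 * pi) - log(v) - 0.5 * log(1 - r^2) - q / 2)
}

.twinLoglik <- function(mz, dz, m, v, a2val, c2val) {
  .bvnLoglik(mz[, 1], mz[, 2], m, v, a2val + c2val) +
    .bvnLoglik(dz[, 1], dz[, 2], m, v, 0.5 * a2val + c2val)
}

.extractPairs <- function(pairs, phenotype) {
  v <- .pairValues(pairs, phenotype)
  list(mz = cbind(v$v1[v$zygosity == "MZ"], v$v2[v$zygosity == "MZ"]),
       dz = cbind(v$v1[v$zygosity == "DZ"], v$v2[v$zygosity == "DZ"]))
}

## Model parameterisation: theta = (m, log v, p, q) where p = a2 + c2 is the
## familial proportion and q the genetic share of it (a2 = p q, c2 = p(1-q)).
## Box constraints p, q in [0, 1] keep a2 + c2 <= 1 without penalties, and
## boundary estimates (a2 = 0) land exactly on the bound.
.modelPar <- function(model) {
  switch(model,
    ACE = list(free = c(TRUE, TRUE), map = function(p, q) c(p * q, p * (1 - q)),
               npar = 4L),
    AE  = list(free = c(TRUE, FALSE), map = function(p, q) c(p, 0),
               npar = 3L),
    CE  = list(free = c(TRUE, FALSE), map = function(p, q) c(0, p),
               npar = 3L),
    E   = list(free = c(FALSE, FALSE), map = function(p, q) c(0, 0),
               npar = 2L),
    stop("unknown model '", model, "'"))
}

#' Fit a univariate twin variance-decomposition model by maximum likelihood
#'
#' Maximises the sum over pairs of bivariate-normal log densities with a
#' single common mean and total variance across twin order and zygosity,
#' and within-pair covariance `(a2 + c2) v` for MZ pairs and
#' `(0.5 a2 + c2) v` for DZ pairs. Components are constrained non-negative;
#' components absent from the chosen model are fixed at exactly zero, and
#' estimates on the zero boundary are reported as exactly zero. The
#' optimiser (bounded quasi-Newton) is run from five fixed start points to
#' guard against boundary-induced local optima.
#'
#' @param pairs a [TwinPairTable-class].
#' @param phenotype phenotype name (defaults to the table's first).
#' @param model `"ACE"`, `"AE"`, `"CE"` or `"E"`.
#' @param residualise optional data.frame of covariates (one row per pair
#'   member in long order) — not implemented at this level; residualise
#'   before building the table if needed.
#' @return A [VarianceFit-class].
#' @examples
#' tw <- simulateTwinPhenotypes(twinSimConfig(200, 200, a2 = 0.5, seed = 1))
#' fitUnivariate(tw, model = "AE")
#' @export
fitUnivariate <- function(pairs, phenotype = phenotypes(pairs)[1],
                          model = c("AE", "ACE", "CE", "E"),
                          residualise = NULL) {
  model <- match.arg(model)
  d <- .extractPairs(pairs, phenotype)
  if (nrow(d$mz) < 2 || nrow(d$dz) < 2)
    stop("need at least 2 complete pairs per zygosity group")
  allv <- c(d$mz, d$dz)
  if (sd(allv) < 1e-12) stop("degenerate (constant) phenotype")
  mp <- .modelPar(model)
  m0 <- mean(allv); lv0 <- log(var(allv))
  nll <- function(th) {
    p <- if (mp$free[1]) th[3] else 0
    q <- if (mp$free[2]) th[if (mp$free[1]) 4 else 3] else 1
    comp <- mp$map(p, q)
    val <- .twinLoglik(d$mz, d$dz, th[1], exp(th[2]), comp[1], comp[2])
    if (!is.finite(val)) 1e10 else -val
  }
  nFree <- 2L + sum(mp$free)
  starts <- list(c(0.2, 0.5), c(0.5, 0.5), c(0.8, 0.5),
                 c(0.5, 0.1), c(0.5, 0.9))
  best <- NULL
  for (s in starts) {
    th0 <- c(m0, lv0, s[seq_len(sum(mp$free))])
    lower <- c(-Inf, lv0 - 20, rep(0, sum(mp$free)))
    upper <- c(Inf, lv0 + 20, rep(1, sum(mp$free)))
    fit <- tryCatch(
      optim(th0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("optimisation failed for model ", model)
  th <- best$par
  p <- if (mp$free[1]) th[3] else 0
  q <- if (mp$free[2]) th[if (mp$free[1]) 4 else 3] else 1
  comp <- mp$map(p, q)
  snap <- function(x) if (abs(x) < 1e-8) 0 else if (abs(x - 1) < 1e-8) 1 else x
  a2v <- snap(comp[1]); c2v <- snap(comp[2])
  new("VarianceFit",
      model = model, a2 = a2v, c2 = c2v, e2 = 1 - a2v - c2v,
      mean = th[1], totalVariance = exp(th[2]), loglik = -best$value,
      npar = mp$npar, nMZ = nrow(d$mz), nDZ = nrow(d$dz),
      ciA2 = c(NA_real_, NA_real_), convergence = best$convergence,
      mzData = d$mz, dzData = d$dz, phenotype = phenotype)
}

#' Twin-cotwin correlation within a zygosity group
#'
#' The primary estimate is the maximum-likelihood intraclass correlation
#' under a bivariate normal with equal means and variances across twin
#' order, with a profile-likelihood confidence interval. Double-entry
#' Pearson and Spearman correlations are also returned, labelled as such.
#'
#' @param pairs a [TwinPairTable-class].
#' @param group `"MZ"` or `"DZ"`.
#' @param phenotype phenotype name.
#' @param level confidence level, default 0.95.
#' @return list with `r` (ML ICC), `ci`, `pearsonDE`, `spearmanDE`, `n`.
#' @export
pairCorrelation <- function(pairs, group = c("MZ", "DZ"),
                            phenotype = phenotypes(pairs)[1],
                            level = 0.95) {
  group <- match.arg(group)
  v <- .pairValues(pairs, phenotype)
  sel <- v$zygosity == group
  x1 <- v$v1[sel]; x2 <- v$v2[sel]
  n <- length(x1)
  if (n < 3) stop("need at least 3 complete pairs in group ", group)
  if (sd(c(x1, x2)) < 1e-12) stop("zero variance; correlation undefined")
  prof <- function(r) {
    opt <- optim(c(mean(c(x1, x2)), log(var(c(x1, x2)))),
                 function(th) -.bvnLoglik(x1, x2, th[1], exp(th[2]), r),
                 method = "BFGS")
    -opt$value
  }
  o <- optimize(function(r) -prof(r), c(-0.999, 0.999))
  rhat <- o$minimum; llmax <- -o$objective
  thresh <- qchisq(level, 1) / 2
  bound <- function(lo, hi) {
    f <- function(r) prof(r) - (llmax - thresh)
    if (f(lo) > 0) return(lo)
    uniroot(f, c(lo, hi), tol = 1e-6)$root
  }
  ci <- c(bound(-0.999, rhat), {
    f <- function(r) prof(r) - (llmax - thresh)
    if (f(0.999) > 0) 0.999 else uniroot(f, c(rhat, 0.999), tol = 1e-6)$root
  })
  de1 <- c(x1, x2); de2 <- c(x2, x1)
  list(r = rhat, ci = ci,
       pearsonDE = cor(de1, de2),
       spearmanDE = cor(de1, de2, method = "spearman"),
       n = n, group = group, level = level)
}

#' Falconer moment estimates of variance components
#'
#' The classical algebra on twin-cotwin correlations: heritability is twice
#' the MZ-DZ correlation difference, `a2 = 2 (rMZ - rDZ)`; then
#' `c2 = rMZ - a2` and `e2 = 1 - rMZ`. Returned both raw (possibly outside
#' `[0, 1]`) and clipped to `[0, 1]`, each labelled.
#'
#' @param rMZ,rDZ twin-cotwin correlations in `[-1, 1]`.
#' @return list with `raw` and `clipped`, each `c(a2, c2, e2)`.
#' @examples
#' falconerEstimates(0.5, 0.25)  # a2 = 0.5, c2 = 0, e2 = 0.5
#' @export
falconerEstimates <- function(rMZ, rDZ) {
  stopifnot(abs(rMZ) <= 1, abs(rDZ) <= 1)
  a2v <- 2 * (rMZ - rDZ)
  c2v <- rMZ - a2v
  e2v <- 1 - rMZ
  raw <- c(a2 = a2v, c2 = c2v, e2 = e2v)
  list(raw = raw, clipped = pmin(pmax(raw, 0), 1))
}

#' Likelihood-ratio comparison of nested twin models
#'
#' The statistic is twice the log-likelihood difference; degrees of freedom
#' equal the difference in free-parameter counts; the p-value comes from
#' the upper tail of the chi-square reference. Because the null value of a
#' variance component lies on the boundary of its parameter space, the
#' asymptotic null is really a 50:50 mixture of chi-square(0) and
#' chi-square(1); the standard chi-square(1) reference is the default (the
#' usual convention in twin software), with the mixture available via
#' `mixture = TRUE`.
#'
#' @param full,reduced [VarianceFit-class] objects fitted to identical data,
#'   `reduced` nested in `full`.
#' @param mixture use the 50:50 boundary mixture reference.
#' @return list with `chisq`, `df`, `p`.
#' @export
compareModels <- function(full, reduced, mixture = FALSE) {
  stopifnot(is(full, "VarianceFit"), is(reduced, "VarianceFit"))
  if (full@npar <= reduced@npar)
    stop("'reduced' must have fewer parameters than 'full'")
  if (full@nMZ != reduced@nMZ || full@nDZ != reduced@nDZ)
    stop("models were fitted to different data")
  chisq <- 2 * (full@loglik - reduced@loglik)
  if (chisq < -1e-6)
    stop("full model has lower likelihood than reduced; refit needed")
  chisq <- max(chisq, 0)
  df <- full@npar - reduced@npar
  p <- pchisq(chisq, df, lower.tail = FALSE)
  if (mixture && df == 1L)
    p <- if (chisq == 0) 1 else 0.5 * pchisq(chisq, 1, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Profile-likelihood confidence interval for a variance component
#'
#' The interval contains all values of the component for which twice the
#' log-likelihood drop from the maximum does not exceed the chi-square(1)
#' quantile, truncated to `[0, 1]`. The lower bound is reported as 0 when
#' the boundary lies inside the interval.
#'
#' @param fit a converged [VarianceFit-class].
#' @param component `"a2"` or `"c2"`; must be free in the fitted model.
#' @param level confidence level, default 0.95.
#' @return numeric(2) interval `(low, high)`; for `"a2"` the interval is
#'   also stored in the returned fit's `ciA2` slot via the attribute
#'   `"fit"`.
#' @export
profileCI <- function(fit, component = c("a2", "c2"), level = 0.95) {
  component <- match.arg(component)
  inModel <- switch(component, a2 = grepl("A", fit@model),
                    c2 = grepl("C", fit@model))
  if (!inModel)
    stop("component ", component, " is fixed at 0 in the ", fit@model,
         " model; profile interval undefined")
  mz <- fit@mzData; dz <- fit@dzData
  other <- switch(fit@model, AE = "none", CE = "none", ACE = "free",
                  stop("no free components"))
  profLL <- function(x) {
    ## maximise over mean, variance (and the other component for ACE)
    if (fit@model == "ACE") {
      o <- optim(c(fit@mean, log(fit@totalVariance), 0.1),
                 function(th) {
                   oth <- th[3]
                   if (oth < 0 || x + oth > 1) return(1e10)
                   a2v <- if (component == "a2") x else oth
                   c2v <- if (component == "a2") oth else x
                   -.twinLoglik(mz, dz, th[1], exp(th[2]), a2v, c2v)
                 }, method = "L-BFGS-B",
                 lower = c(-Inf, log(fit@totalVariance) - 20, 0),
                 upper = c(Inf, log(fit@totalVariance) + 20, 1 - x))
    } else {
      a2v <- if (fit@model == "AE") x else 0
      c2v <- if (fit@model == "CE") x else 0
      o <- optim(c(fit@mean, log(fit@totalVariance)),
                 function(th) -.twinLoglik(mz, dz, th[1], exp(th[2]),
                                           a2v, c2v),
                 method = "BFGS")
    }
    -o$value
  }
  est <- slot(fit, component)
  thresh <- qchisq(level, 1) / 2
  llmax <- fit@loglik
  f <- function(x) profLL(x) - (llmax - thresh)
  lo <- if (est <= 1e-10 || f(0) >= 0) 0 else
    uniroot(f, c(0, est), tol = 1e-6)$root
  hi <- if (est >= 1 - 1e-10 || f(1 - 1e-9) >= 0) 1 else
    uniroot(f, c(max(est, 1e-9), 1 - 1e-9), tol = 1e-6)$root
  ci <- c(lo, hi)
  if (component == "a2") {
    fit@ciA2 <- ci
    attr(ci, "fit") <- fit
  }
  ci
}
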
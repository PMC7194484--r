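## Power to detect heritability in an AE twin design, by the noncentral
## chi-square LRT approximation and by Monte Carlo.

## ML discrepancy of fitting model covariance S0 to population covariance Sg
.mlDiscrepancy <- function(S0, Sg) {
  p <- nrow(Sg)
  log(det(S0)) - log(det(Sg)) + sum(diag(Sg %*% solve(S0))) - p
}

#' Power to detect a2 in an AE twin model
#'
#' For the noncentral-chi-square method, the implied MZ and DZ pair
#' covariance matrices are built under the generating model (unit total
#' variance, correlations `a2` and `a2/2`); the E-only model (equal
#' uncorrelated variances) is fitted to them by minimising the combined ML
#' discrepancy, giving the likelihood-ratio noncentrality
#' `lambda = nMZ * F_MZ + nDZ * F_DZ`; power is the upper-tail probability
#' of a noncentral chi-square(1, lambda) beyond the central chi-square(1)
#' critical value. Because phenotypes are standardized, power depends only
#' on the variance proportions. For the simulation method, `nReps` twin
#' datasets are generated under the AE model, the AE-vs-E likelihood-ratio
#' test is run on each, and power is the rejection fraction.
#'
#' The default reference distribution is the standard chi-square(1); since
#' a2 = 0 lies on the boundary of the parameter space, the 50:50
#' chi-square(0):chi-square(1) mixture is available via `mixture = TRUE`
#' (it lowers the critical value and raises power).
#'
#' @param nMZ,nDZ numbers of MZ and DZ pairs.
#' @param a2True generating heritability, in `[0, 1)`.
#' @param alpha test level, default 0.05.
#' @param method `"ncp"` or `"simulation"`.
#' @param nReps simulation replicates, default 5000.
#' @param mixture use the boundary mixture reference.
#' @param seed RNG seed for the simulation method.
#' @return A [PowerResult-class].
#' @examples
#' powerAE(96, 98, a2True = 0.25)
#' @export
powerAE <- function(nMZ, nDZ, a2True, alpha = 0.05,
                    method = c("ncp", "simulation"),
                    nReps = 5000, mixture = FALSE, seed = NULL) {
  method <- match.arg(method)
  stopifnot(nMZ + nDZ >= 10, a2True >= 0, alpha > 0, alpha < 1)
  if (a2True >= 1)
    stop("a2True = 1 implies a degenerate DZ pair covariance")
  crit <- if (mixture) qchisq(1 - 2 * alpha, 1) else qchisq(1 - alpha, 1)
  if (method == "ncp") {
    Smz <- matrix(c(1, a2True, a2True, 1), 2)
    Sdz <- matrix(c(1, a2True / 2, a2True / 2, 1), 2)
    obj <- function(s2)
      nMZ * .mlDiscrepancy(diag(s2, 2), Smz) +
      nDZ * .mlDiscrepancy(diag(s2, 2), Sdz)
    lambda <- optimize(obj, c(1e-3, 10))$objective
    if (a2True == 0) lambda <- 0
    pow <- pchisq(crit, 1, ncp = lambda, lower.tail = FALSE)
    if (mixture && a2True == 0) pow <- alpha  # size under the mixture null
    new("PowerResult", nMZ = nMZ, nDZ = nDZ, a2True = a2True,
        alpha = alpha, power = pow, method = "ncp",
        nReps = NA_real_, lambda = lambda, mixture = mixture)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rej <- logical(nReps)
    for (i in seq_len(nReps)) {
      rej[i] <- .lrtAEvsE(nMZ, nDZ, a2True) > crit
    }
    new("PowerResult", nMZ = nMZ, nDZ = nDZ, a2True = a2True,
        alpha = alpha, power = mean(rej), method = "simulation",
        nReps = nReps, lambda = NA_real_, mixture = mixture)
  }
}

## One Monte-Carlo replicate of the AE-vs-E LRT statistic: simulate a twin
## sample under (a2, e2 = 1 - a2), fit both models. The E model has a
## closed-form MLE; the AE model is profiled with a single quasi-Newton run
## started at the clipped Falconer estimate (adequate for power counting).
.lrtAEvsE <- function(nMZ, nDZ, a2True) {
  zyg <- rep(c("MZ", "DZ"), c(nMZ, nDZ))
  aShared <- rnorm(nMZ + nDZ)
  mix <- function() ifelse(zyg == "MZ", aShared,
                           sqrt(0.5) * aShared + sqrt(0.5) * rnorm(nMZ + nDZ))
  e2v <- 1 - a2True
  x1 <- sqrt(a2True) * mix() + sqrt(e2v) * rnorm(nMZ + nDZ)
  x2 <- sqrt(a2True) * mix() + sqrt(e2v) * rnorm(nMZ + nDZ)
  mz <- cbind(x1[zyg == "MZ"], x2[zyg == "MZ"])
  dz <- cbind(x1[zyg == "DZ"], x2[zyg == "DZ"])
  allv <- c(x1, x2)
  mE <- mean(allv); vE <- mean((allv - mE)^2)
  llE <- .twinLoglik(mz, dz, mE, vE, 0, 0)
  rmz <- cor(mz[, 1], mz[, 2]); rdz <- cor(dz[, 1], dz[, 2])
  a0 <- min(0.95, max(0.05, 2 * (rmz - rdz)))
  o <- optim(c(mE, log(vE), a0),
             function(th) -.twinLoglik(mz, dz, th[1], exp(th[2]), th[3], 0),
             method = "L-BFGS-B",
             lower = c(-Inf, log(vE) - 10, 0),
             upper = c(Inf, log(vE) + 10, 0.9999))
  max(0, 2 * (-o$value - llE))
}

#' Power curve over sample sizes and heritabilities
#'
#' Evaluates [powerAE()] on a grid of total pair counts (split into MZ and
#' DZ by `mzFraction`) and generating heritabilities, returning a
#' plot-ready long table.
#'
#' @param nGrid integer vector of total pair counts.
#' @param mzFraction proportion of pairs that are MZ, default 0.5.
#' @param a2Values heritabilities to trace, default
#'   `c(0.15, 0.2, 0.25, 0.3, 0.35)`.
#' @param alpha test level.
#' @param mixture passed to [powerAE()].
#' @return data.frame with columns `n`, `nMZ`, `nDZ`, `a2`, `power`.
#' @export
powerCurve <- function(nGrid, mzFraction = 0.5,
                       a2Values = c(0.15, 0.2, 0.25, 0.3, 0.35),
                       alpha = 0.05, mixture = FALSE) {
  stopifnot(all(nGrid >= 10), mzFraction > 0, mzFraction < 1)
  rows <- list()
  for (a2v in a2Values) for (n in nGrid) {
    nmz <- round(n * mzFraction); ndz <- n - nmz
    pr <- powerAE(nmz, ndz, a2v, alpha = alpha, mixture = mixture)
    rows[[length(rows) + 1L]] <-
      data.frame(n = n, nMZ = nmz, nDZ = ndz, a2 = a2v, power = pr@power)
  }
  do.call(rbind, rows)
}

#' Plot a power curve table
#'
#' Line plot of power against total pairs, one line per heritability, in
#' the layout of a twin-design power figure. Requires ggplot2.
#'
#' @param curve output of [powerCurve()].
#' @param vlines optional vertical reference lines (total pair counts).
#' @return a ggplot object.
#' @export
plotPowerCurve <- function(curve, vlines = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  gg <- ggplot2::ggplot(curve,
          ggplot2::aes(x = n, y = power, colour = factor(a2))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(x = "Total twin pairs", y = "Power",
                  colour = expression(a^2)) +
    ggplot2::theme_minimal()
  if (!is.null(vlines))
    gg <- gg + ggplot2::geom_vline(xintercept = vlines, linetype = "dotted")
  gg
}
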
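test_that("model likelihood matches a brute-force bivariate-normal oracle", {
  set.seed(1)
  mz <- cbind(rnorm(5), rnorm(5))
  dz <- cbind(rnorm(5), rnorm(5))
  tw <- makePairs(mz[, 1], mz[, 2], dz[, 1], dz[, 2])
  for (model in c("AE", "ACE", "CE", "E")) {
    fit <- fitUnivariate(tw, model = model)
    expect_equal(fit@loglik,
                 oracleTwinLoglik(mz, dz, fit@mean, fit@totalVariance,
                                  fit@a2, fit@c2),
                 tolerance = 1e-9, info = model)
  }
})

test_that("AE fit recovers a generating heritability of 0.5", {
  tw <- simulateTwinPhenotypes(twinSimConfig(1000, 1000, a2 = 0.5, seed = 42))
  fit <- fitUnivariate(tw, model = "AE")
  expect_equal(fit@convergence, 0)
  expect_lt(abs(a2(fit) - 0.5), 0.05)
  expect_equal(a2(fit) + c2(fit) + e2(fit), 1, tolerance = 1e-8)
})

test_that("independent twins drive a2 to the zero boundary, reported exactly 0", {
  set.seed(7)
  m1 <- rnorm(150); m2 <- rnorm(150); d1 <- rnorm(150); d2 <- rnorm(150)
  tw <- makePairs(m1, m2, d1, d2)
  fit <- fitUnivariate(tw, model = "AE")
  expect_identical(a2(fit), 0)
})

test_that("estimates are invariant to within-pair label order", {
  tw <- simulateTwinPhenotypes(twinSimConfig(80, 80, a2 = 0.4, seed = 6))
  p <- pairData(tw)
  swap <- seq(1, nrow(p), by = 3)
  tmp <- p$y_1[swap]; p$y_1[swap] <- p$y_2[swap]; p$y_2[swap] <- tmp
  tw2 <- TwinPairTable(p, phenotypes = "y")
  f1 <- fitUnivariate(tw, model = "AE")
  f2 <- fitUnivariate(tw2, model = "AE")
  expect_lt(abs(a2(f1) - a2(f2)), 1e-8)
  expect_lt(abs(f1@loglik - f2@loglik), 1e-8)
})

test_that("Falconer estimates follow the classical algebra", {
  expect_equal(falconerEstimates(0.5, 0.25)$raw,
               c(a2 = 0.5, c2 = 0, e2 = 0.5))
  expect_equal(falconerEstimates(0, 0)$raw, c(a2 = 0, c2 = 0, e2 = 1))
  # twin-cotwin correlations like the handedness inventory row
  expect_equal(falconerEstimates(0.18, 0.13)$raw,
               c(a2 = 0.10, c2 = 0.08, e2 = 0.82), tolerance = 1e-12)
  # negative raw estimates are preserved and the clipped version labelled
  f <- falconerEstimates(0.1, 0.3)
  expect_lt(f$raw[["a2"]], 0)
  expect_equal(f$clipped[["a2"]], 0)
})

test_that("identical fits compare with zero chi-square and p = 1", {
  tw <- simulateTwinPhenotypes(twinSimConfig(50, 50, a2 = 0.3, seed = 3))
  ae <- fitUnivariate(tw, model = "AE")
  ace <- fitUnivariate(tw, model = "ACE")
  cmp <- compareModels(ace, ae)
  expect_gte(cmp$p, 0.0)
  e0 <- fitUnivariate(tw, model = "E")
  same <- compareModels(ae, e0)
  expect_equal(same$df, 1)
  # chi-square is twice the log-likelihood difference
  expect_equal(same$chisq, 2 * (ae@loglik - e0@loglik), tolerance = 1e-10)
  # mixture reference halves a nonzero p
  if (same$chisq > 0)
    expect_equal(compareModels(ae, e0, mixture = TRUE)$p, same$p / 2)
})

test_that("profile interval is defined only for free components and brackets the MLE", {
  tw <- simulateTwinPhenotypes(twinSimConfig(200, 200, a2 = 0.4, seed = 11))
  fit <- fitUnivariate(tw, model = "AE")
  ci <- profileCI(fit, "a2")
  expect_lt(ci[1], a2(fit))
  expect_gt(ci[2], a2(fit))
  expect_gte(ci[1], 0)
  expect_lte(ci[2], 1)
  expect_error(profileCI(fit, "c2"), "fixed at 0")
})

test_that("boundary estimates report a profile interval with a zero lower bound", {
  set.seed(13)
  tw <- makePairs(rnorm(120), rnorm(120), rnorm(120), rnorm(120))
  fit <- fitUnivariate(tw, model = "AE")
  ci <- profileCI(fit, "a2")
  expect_identical(ci[1], 0)
  expect_lt(ci[2], 0.5)
})

test_that("ML intraclass correlation recovers generator truth and extremes", {
  v <- rnorm(60)
  twEq <- makePairs(v[1:30], v[1:30], v[31:60], v[31:60])
  r <- pairCorrelation(twEq, "MZ")
  expect_gt(r$r, 0.99)
  expect_equal(r$pearsonDE, 1)

  tw <- simulateTwinPhenotypes(twinSimConfig(2000, 10, a2 = 0.5, seed = 19))
  est <- pairCorrelation(tw, "MZ")
  expect_lt(abs(est$r - 0.5), 0.03)
  expect_true(est$ci[1] < est$r & est$r < est$ci[2])
})

test_that("shared-environment data prefer CE over AE by likelihood", {
  tw <- simulateTwinPhenotypes(twinSimConfig(400, 400, a2 = 0, c2 = 0.35,
                                             seed = 23))
  ae <- fitUnivariate(tw, model = "AE")
  ce <- fitUnivariate(tw, model = "CE")
  expect_gt(ce@loglik, ae@loglik)
  # and the CE fit recovers the shared-environment proportion
  expect_lt(abs(c2(ce) - 0.35), 0.08)
})

test_that("implied twin correlations follow the standardization identity", {
  for (seed in 1:3) {
    tw <- simulateTwinPhenotypes(twinSimConfig(150, 150, a2 = 0.3, c2 = 0.2,
                                               seed = seed))
    fit <- fitUnivariate(tw, model = "ACE")
    rmz <- a2(fit) + c2(fit)
    rdz <- 0.5 * a2(fit) + c2(fit)
    expect_equal(rmz, fit@a2 + fit@c2, tolerance = 1e-12)
    expect_gte(rmz, rdz)
    expect_lte(rmz, 1)
  }
})
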
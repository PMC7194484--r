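relT <- seq(-12, 18, by = 0.04)

test_that("constant difference gives identical mean and peak LIs", {
  ep <- makeEpochSet(matrix(2, 1, length(relT)), relT)
  ep <- computeTrialLI(ep)
  expect_equal(trialLI(ep, "mean"), 2)
  expect_equal(trialLI(ep, "peak"), 2)
})

test_that("antisymmetric difference: zero mean LI, peak from the earliest extremum", {
  d <- ifelse(relT >= 4 & relT < 9, 3, ifelse(relT >= 9 & relT <= 14, -3, 0))
  ep <- computeTrialLI(makeEpochSet(matrix(d, 1), relT))
  # 126 samples at +3 (4 <= t < 9), 126 at -3 (9 <= t <= 14)... the grid is
  # symmetric about 9 so positives and negatives balance except t = 9 itself
  nPos <- sum(relT >= 4 & relT < 9)
  nNeg <- sum(relT >= 9 & relT <= 14)
  expected <- (3 * nPos - 3 * nNeg) / (nPos + nNeg)
  expect_equal(trialLI(ep, "mean"), expected, tolerance = 1e-12)
  # all POI samples tie at |3|; earliest (t = 4) wins, window truncated to [4, 5]
  expect_equal(trialLI(ep, "peak"), 3)
})

test_that("sampled sine wave matches the brute-force grid oracle", {
  d <- ifelse(relT >= 4 & relT <= 14, sin(pi * (relT - 4) / 10), 0)
  ep <- computeTrialLI(makeEpochSet(matrix(d, 1), relT))
  # frozen values from an independent scan of the sampled grid
  expect_equal(trialLI(ep, "mean"), 0.634075094388, tolerance = 1e-9)
  expect_equal(trialLI(ep, "peak"), 0.982980224806, tolerance = 1e-9)
})

test_that("an empty period of interest is a configuration error", {
  ep <- makeEpochSet(matrix(1, 1, length(relT)), relT)
  expect_error(computeTrialLI(ep, periodOfInterest(start = 20, end = 25)),
               "malformed configuration")
})

test_that("rejected trials carry NA trial LIs", {
  ep <- makeEpochSet(matrix(1, 2, length(relT), byrow = TRUE), relT,
                     accepted = c(TRUE, FALSE))
  ep <- computeTrialLI(ep)
  expect_false(is.na(trialLI(ep)[1]))
  expect_true(is.na(trialLI(ep)[2]))
})

test_that("mean and peak LIs share the sign convention on monophasic signals", {
  set.seed(4)
  for (sgn in c(1, -1)) {
    shape <- exp(-((relT - 8) / 3)^2)
    M <- t(vapply(1:6, function(i) sgn * runif(1, 0.5, 2) * shape,
                  numeric(length(relT))))
    ep <- computeTrialLI(makeEpochSet(M, relT))
    expect_true(all(sign(trialLI(ep, "mean")) == sgn))
    expect_true(all(sign(trialLI(ep, "peak")) == sgn))
  }
})
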
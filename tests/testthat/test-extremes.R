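test_that("Welch statistic matches the textbook formula exactly", {
  # construct a pair table whose MZ/DZ cotwin sets are known fixed vectors
  coMZ <- c(6.1, 7.3, 5.8, 8.2, 6.6, 7.7, 5.2)
  coDZ <- c(6.9, 7.1, 6.2, 8.8, 7.4, 6.0, 7.9, 5.5)
  tw <- makePairs(mz1 = rep(-2, length(coMZ)), mz2 = coMZ,
                  dz1 = rep(-2, length(coDZ)), dz2 = coDZ)
  res <- extremesTTest(tw, cutoff = 0, direction = "below")
  # only twin1 entries fall below the cutoff, so cotwins are exactly coMZ/coDZ
  o <- oracleWelch(coMZ, coDZ)
  expect_equal(res@t, o$t, tolerance = 1e-12)
  expect_equal(res@df, o$df, tolerance = 1e-12)
  expect_equal(res@p, o$p, tolerance = 1e-12)
  expect_equal(res@nProbandsMZ, length(coMZ))
  expect_equal(res@cotwinMeanMZ, mean(coMZ))
})

test_that("identical cotwin distributions give t = 0 and p = 1", {
  co <- rnorm(40)
  tw <- makePairs(mz1 = rep(-1, 40), mz2 = co,
                  dz1 = rep(-1, 40), dz2 = co)
  res <- extremesTTest(tw, cutoff = 0, direction = "below")
  expect_equal(res@t, 0, tolerance = 1e-12)
  expect_equal(res@p, 1, tolerance = 1e-12)
})

test_that("both-extreme pairs contribute both members under double entry, one under single entry", {
  tw <- makePairs(mz1 = c(-3, -2, 1), mz2 = c(-1, 2, -2),
                  dz1 = c(-2, -1, 3), dz2 = c(-3, 2, -1))
  de <- extremesTTest(tw, cutoff = 0, direction = "below")
  # MZ: pair1 both below (2 probands), pair2 twin1, pair3 twin2 -> 4
  expect_equal(de@nProbandsMZ, 4)
  expect_equal(de@nProbandsDZ, 4)
  se <- extremesTTest(tw, cutoff = 0, direction = "below", singleEntry = TRUE)
  expect_equal(se@nProbandsMZ, 3)
  expect_equal(se@nProbandsDZ, 3)
})

test_that("under strong heritability MZ cotwins regress less than DZ cotwins", {
  tw <- simulateTwinPhenotypes(twinSimConfig(4000, 4000, a2 = 0.8, seed = 41))
  res <- extremesTTest(tw, cutoff = -1, direction = "below")
  # population mean 0; probands average below -1; MZ cotwins stay lower
  expect_lt(res@cotwinMeanMZ, res@cotwinMeanDZ)
  expect_lt(res@cotwinMeanMZ, 0)
  # and cotwins regress toward the mean relative to probands
  expect_gt(res@cotwinMeanMZ, res@probandMeanMZ)
})

test_that("pure-chance phenotypes leave cotwin means near the population mean", {
  tw <- simulateTwinPhenotypes(twinSimConfig(5000, 5000, a2 = 0, seed = 43))
  res <- extremesTTest(tw, cutoff = -1, direction = "below")
  expect_lt(abs(res@cotwinMeanMZ), 0.06)
  expect_lt(abs(res@cotwinMeanDZ), 0.06)
})

test_that("empty proband groups are an error, not a silent p-value", {
  tw <- makePairs(mz1 = c(1, 2, 3), mz2 = c(2, 3, 4),
                  dz1 = c(1, 2, 3), dz2 = c(2, 3, 4))
  expect_error(extremesTTest(tw, cutoff = -5, direction = "below"),
               "fewer than 2 probands")
})

test_that("double entry inflates the null rejection rate, single entry does not", {
  # both-extreme pairs contribute two mutually conditioned cotwin values,
  # so the double-entry Welch test is anticonservative under the null
  set.seed(45)
  pDouble <- pSingle <- numeric(400)
  for (i in 1:400) {
    tw <- simulateTwinPhenotypes(twinSimConfig(100, 100, a2 = 0))
    pDouble[i] <- extremesTTest(tw, cutoff = -0.5, direction = "below")@p
    pSingle[i] <- extremesTTest(tw, cutoff = -0.5, direction = "below",
                                singleEntry = TRUE)@p
  }
  expect_gt(mean(pDouble < 0.05), 0.07)
  expect_lt(abs(mean(pSingle < 0.05) - 0.05), 0.03)
})

test_that("direction 'above' selects the upper tail", {
  tw <- makePairs(mz1 = c(5, -1, 6), mz2 = c(0.2, -0.1, 0.4),
                  dz1 = c(7, -2, 8), dz2 = c(1.1, 0.9, 1.3))
  res <- extremesTTest(tw, cutoff = 4, direction = "above")
  expect_equal(res@nProbandsMZ, 2)
  expect_equal(res@probandMeanMZ, mean(c(5, 6)))
})
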
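test_that("pure-chance phenotypes show near-zero twin correlations", {
  tw <- simulateTwinPhenotypes(twinSimConfig(1500, 1500, a2 = 0, c2 = 0,
                                             seed = 51))
  rMZ <- pairCorrelation(tw, "MZ")$pearsonDE
  rDZ <- pairCorrelation(tw, "DZ")$pearsonDE
  expect_lt(abs(rMZ), 2 / sqrt(1500))
  expect_lt(abs(rDZ), 2 / sqrt(1500))
})

test_that("fully genetic phenotypes approach rMZ = 1, rDZ = 0.5", {
  tw <- simulateTwinPhenotypes(twinSimConfig(3000, 3000, a2 = 1, seed = 52))
  expect_gt(pairCorrelation(tw, "MZ")$pearsonDE, 0.99)
  expect_lt(abs(pairCorrelation(tw, "DZ")$pearsonDE - 0.5), 0.04)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- simulateTwinPhenotypes(twinSimConfig(50, 50, a2 = 0.3, seed = 53))
  b <- simulateTwinPhenotypes(twinSimConfig(50, 50, a2 = 0.3, seed = 53))
  expect_identical(pairData(a), pairData(b))
  ra <- simulateDopplerSession(dopplerSimConfig(nTrials = 4, seed = 54))
  rb <- simulateDopplerSession(dopplerSimConfig(nTrials = 4, seed = 54))
  expect_identical(ra@left, rb@left)
  expect_identical(attr(ra, "groundTruth")$events,
                   attr(rb, "groundTruth")$events)
})

test_that("the J-shape map is monotone, bounded and preserves rank structure", {
  tw <- simulateTwinPhenotypes(twinSimConfig(800, 800, a2 = 0.4, seed = 55))
  set.seed(55)  # regenerate the same latent draws through the same stream
  twJ <- simulateTwinPhenotypes(twinSimConfig(800, 800, a2 = 0.4,
                                              marginal = "jshape", seed = 55))
  pj <- pairData(twJ)
  expect_true(all(pj$y_1 >= 0 & pj$y_1 <= 10))
  # heavy right-hand mass: the distribution is J-shaped toward 10
  expect_gt(mean(pj$y_1 > 8), 0.4)
  # Spearman twin-cotwin correlation survives the transform
  p <- pairData(tw)
  sLat <- cor(p$y_1[p$zygosity == "MZ"], p$y_2[p$zygosity == "MZ"],
              method = "spearman")
  sJ <- cor(pj$y_1[pj$zygosity == "MZ"], pj$y_2[pj$zygosity == "MZ"],
            method = "spearman")
  expect_lt(abs(sLat - sJ), 0.02)
})

test_that("variance-component configs are validated", {
  expect_error(twinSimConfig(10, 10, a2 = 0.7, c2 = 0.5), "sum to at most 1")
  expect_error(twinSimConfig(10, 10, a2 = -0.1), "non-negative")
  expect_error(dopplerSimConfig(interTrial = 20), "overlap")
  expect_error(dopplerSimConfig(dropoutProb = 0.6, artifactProb = 0.6),
               "at most 1")
})

test_that("noise-free sessions recover the true LI within 1 percent", {
  for (delta in c(2, 4)) {
    rec <- simulateDopplerSession(dopplerSimConfig(
      nTrials = 10, noiseSd = 0, driftSd = 0, responseDelta = delta,
      seed = 56))
    ep <- computeTrialLI(epochAndReject(preprocessRecording(rec)))
    li <- as.data.frame(summarizeSubject(ep))$liMean
    expect_lt(abs(li - delta) / delta, 0.01)
  }
})

test_that("flipping the response sign flips subject categories left/right", {
  mk <- function(delta) {
    rec <- simulateDopplerSession(dopplerSimConfig(
      nTrials = 12, noiseSd = 0, driftSd = 0, responseDelta = delta,
      seed = 57))
    as.data.frame(summarizeSubject(
      computeTrialLI(epochAndReject(preprocessRecording(rec)))))
  }
  pos <- mk(2); neg <- mk(-2)
  expect_equal(pos$category, "left")
  expect_equal(neg$category, "right")
  expect_equal(pos$liMean, -neg$liMean, tolerance = 0.02)
  expect_equal(pos$binaryTypical, "typical")
  expect_equal(neg$binaryTypical, "atypical")
})

test_that("rejection counts equal the injection log under heavy corruption", {
  rec <- simulateDopplerSession(dopplerSimConfig(
    nTrials = 30, artifactProb = 0.2, dropoutProb = 0.1, invalidProb = 0.1,
    seed = 58))
  gt <- attr(rec, "groundTruth")
  ep <- epochAndReject(preprocessRecording(rec))
  expect_equal(sum(!accepted(ep)), nrow(gt$events))
  expect_equal(which(!accepted(ep)), gt$events$trial)
})

test_that("generator-fit round trip: components within 2 SE in most replicates", {
  grid <- expand.grid(a2 = c(0, 0.25, 0.5), c2 = c(0, 0.2))
  for (g in seq_len(nrow(grid))) {
    ests <- vapply(1:25, function(i) {
      tw <- simulateTwinPhenotypes(twinSimConfig(
        150, 150, a2 = grid$a2[g], c2 = grid$c2[g], seed = 600 + 25 * g + i))
      fit <- fitUnivariate(tw, model = "ACE")
      c(a2(fit), c2(fit))
    }, numeric(2))
    se <- apply(ests, 1, sd)
    inA <- abs(ests[1, ] - grid$a2[g]) <= 2 * max(se[1], 0.02)
    inC <- abs(ests[2, ] - grid$c2[g]) <= 2 * max(se[2], 0.02)
    expect_gte(mean(inA), 0.8)
    expect_gte(mean(inC), 0.8)
  }
})
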
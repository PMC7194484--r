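test_that("heart-cycle integration flattens pure pulsatility on a constant baseline", {
  t <- seq(0, 60, by = 0.04)
  v <- 50 + 10 * sin(2 * pi * 1.5 * t)
  rec <- VelocityRecording("const", t, v, v, markerTime = 30)
  out <- preprocessRecording(rec)
  interior <- t > 2 & t < 58
  expect_lt(max(abs(out@left[interior] - 100)), 0.5)
  expect_lt(max(abs(out@right[interior] - 100)), 0.5)
  # integration preserves the overall channel mean to within 0.5%
  expect_lt(abs(out@meta$channelMeanLeft - mean(v)) / mean(v), 0.005)
})

test_that("single-sample dropouts are replaced by the flanking mean; runs are flagged", {
  v <- c(48, 48, 0, 52, 52)
  res <- twinlat:::.handleDropouts(v, threshold = 0)
  expect_equal(res$v[3], 50)
  expect_false(any(res$prolonged))

  v2 <- c(50, 50, 0, 0, 0, 50, 50)
  res2 <- twinlat:::.handleDropouts(v2, threshold = 0)
  expect_equal(res2$prolonged, c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("flat signal raises an unusable-recording error", {
  t <- seq(0, 30, by = 0.04)
  rec <- VelocityRecording("flat", t, rep(50, length(t)), rep(50, length(t)),
                           markerTime = 15)
  expect_error(preprocessRecording(rec), "unusable")
})

test_that("non-uniform time grids are rejected at construction", {
  t <- c(seq(0, 10, by = 0.04), seq(10.1, 20, by = 0.05))
  expect_error(VelocityRecording("bad", t, seq_along(t), seq_along(t),
                                 markerTime = 5),
               "uniform")
})

test_that("cycle-integrated trace matches the generator's stored cycle means", {
  rec <- simulateDopplerSession(dopplerSimConfig(
    nTrials = 6, noiseSd = 0, driftSd = 0.05, responseDelta = 2, seed = 3))
  gt <- attr(rec, "groundTruth")
  out <- preprocessRecording(rec)
  # undo the percent scaling to compare on the raw cm/s scale
  intL <- approx(out@time, out@left * out@meta$channelMeanLeft / 100,
                 xout = gt$cycleMid)$y
  intR <- approx(out@time, out@right * out@meta$channelMeanRight / 100,
                 xout = gt$cycleMid)$y
  ok <- is.finite(gt$cycleMid)
  expect_lt(max(abs(intL[ok] - gt$cycleMeanLeft[ok])), 0.6)
  expect_lt(max(abs(intR[ok] - gt$cycleMeanRight[ok])), 0.6)
  # and closely on average
  expect_lt(mean(abs(intL[ok] - gt$cycleMeanLeft[ok])), 0.2)
})

test_that("pipeline is invariant to overall channel gain", {
  rec <- simulateDopplerSession(dopplerSimConfig(
    nTrials = 8, responseDelta = 2, seed = 9))
  scaled <- initialize(rec, left = rec@left * 3.7, right = rec@right * 3.7)
  ep1 <- computeTrialLI(epochAndReject(preprocessRecording(rec)))
  ep2 <- computeTrialLI(epochAndReject(preprocessRecording(scaled)))
  expect_equal(SummarizedExperiment::assay(ep1, "diff"),
               SummarizedExperiment::assay(ep2, "diff"), tolerance = 1e-8)
  expect_equal(trialLI(ep1), trialLI(ep2), tolerance = 1e-8)
  s1 <- as.data.frame(summarizeSubject(ep1))
  s2 <- as.data.frame(summarizeSubject(ep2))
  expect_identical(s1$category, s2$category)
})
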
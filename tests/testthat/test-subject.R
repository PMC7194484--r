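test_that("zero-variance trial LIs give a degenerate CI and a left category", {
  s <- subjectsFromTrialLIs(data.frame(subjectId = "a",
                                       trialLIMean = rep(2.5, 16)))
  d <- as.data.frame(s)
  expect_equal(d$liMean, 2.5)
  expect_equal(d$se, 0)
  expect_equal(d$category, "left")
  expect_equal(d$binaryTypical, "typical")
  expect_false(d$excluded)
})

test_that("t-interval summary matches the closed form", {
  x <- as.numeric(scale(1:20)) * 2 + 0.1   # exact mean 0.1, sample SD 2
  s <- subjectsFromTrialLIs(data.frame(subjectId = "a", trialLIMean = x))
  d <- as.data.frame(s)
  se <- 2 / sqrt(20)
  expect_equal(d$se, se, tolerance = 1e-12)
  expect_equal(d$ciLow, 0.1 - qt(0.975, 19) * se, tolerance = 1e-12)
  expect_equal(d$ciHigh, 0.1 + qt(0.975, 19) * se, tolerance = 1e-12)
  expect_equal(d$category, "bilateral")
  expect_equal(d$binaryTypical, "atypical")
})

test_that("subjects with fewer than 12 accepted trials are excluded", {
  s <- subjectsFromTrialLIs(data.frame(subjectId = "a",
                                       trialLIMean = rnorm(11)))
  d <- as.data.frame(s)
  expect_true(d$excluded)
  expect_equal(d$exclusionReason, "too_few_trials")
  # a single trial leaves the SE undefined and the subject excluded
  s1 <- subjectsFromTrialLIs(data.frame(subjectId = "b", trialLIMean = 1))
  expect_true(as.data.frame(s1)$excluded)
  expect_true(is.na(as.data.frame(s1)$se))
})

test_that("odd/even half LIs follow presentation order of accepted trials", {
  x <- c(1, 5, 2, 6, 3, 7, 4, 8, 1, 5, 2, 6)
  d <- as.data.frame(subjectsFromTrialLIs(
    data.frame(subjectId = "a", trialLIMean = x)))
  expect_equal(d$liOdd, mean(x[seq(1, 11, 2)]))
  expect_equal(d$liEven, mean(x[seq(2, 12, 2)]))
})

test_that("single-pass 5 SD exclusion flags planted outliers only", {
  set.seed(8)
  base <- rnorm(100, 2, 1)
  lis <- c(base, mean(base) + 8 * sd(base))
  tl <- data.frame(subjectId = rep(sprintf("s%03d", seq_along(lis)), each = 14),
                   trialLIMean = rep(lis, each = 14))
  subj <- subjectsFromTrialLIs(tl)
  out <- applySampleExclusions(subj, sdLimit = 5)
  d <- as.data.frame(out)
  # direct z-score oracle on the subject means
  z <- abs(d$liMean - mean(d$liMean[!as.data.frame(subj)$excluded])) /
    sd(d$liMean[!as.data.frame(subj)$excluded])
  expect_equal(which(d$exclusionReason == "outlier_5sd"), which(z > 5))
  expect_equal(sum(d$exclusionReason == "outlier_5sd"), 1L)

  # no outliers: output equals input
  out2 <- applySampleExclusions(subj[seq_along(base)], sdLimit = 5)
  expect_equal(as.data.frame(out2), as.data.frame(subj[seq_along(base)]))
})

test_that("two planted outliers at opposite tails are both flagged", {
  set.seed(9)
  base <- rnorm(200, 1, 0.5)
  m <- mean(base); s <- sd(base)
  lis <- c(base, m + 6.5 * s, m - 6.5 * s)
  tl <- data.frame(subjectId = rep(sprintf("s%03d", seq_along(lis)), each = 14),
                   trialLIMean = rep(lis, each = 14))
  out <- as.data.frame(applySampleExclusions(subjectsFromTrialLIs(tl)))
  flagged <- which(out$exclusionReason == "outlier_5sd")
  expect_setequal(flagged, c(201L, 202L))
})

test_that("split-half reliability handles identity, antisymmetry and degeneracy", {
  set.seed(3)
  x <- rnorm(30, 2, 1)
  mk <- function(odd, even) {
    d <- data.frame(subjectId = sprintf("s%02d", seq_along(odd)),
                    nAccepted = 16, liMean = (odd + even) / 2,
                    liPeak = (odd + even) / 2,
                    se = 0.1, sePeak = 0.1,
                    ciLow = (odd + even) / 2 - 1, ciHigh = (odd + even) / 2 + 1,
                    ciLowPeak = 0, ciHighPeak = 1,
                    category = "bilateral", binaryTypical = "atypical",
                    liOdd = odd, liEven = even,
                    meanLeftFlow = 100, meanRightFlow = 100,
                    excluded = FALSE, exclusionReason = "none",
                    stringsAsFactors = FALSE)
    new("SubjectLaterality", data = d)
  }
  expect_equal(splitHalfReliability(mk(x, x))$r, 1)
  expect_equal(splitHalfReliability(mk(x, -x))$r, -1)
  expect_error(splitHalfReliability(mk(rep(1, 30), x)), "zero variance")
  # Spearman-Brown is reported alongside, not substituted
  rel <- splitHalfReliability(mk(x, x + rnorm(30)))
  expect_equal(rel$spearmanBrown, 2 * rel$r / (1 + rel$r))
})

test_that("category coheres with the confidence interval over a simulated cohort", {
  set.seed(12)
  tl <- simulateTrialLICohort(80, 16, mu = 1.5, sdSubject = 2, sdNoise = 5,
                              seed = 12)
  d <- as.data.frame(subjectsFromTrialLIs(tl))
  expect_true(all(d$category[d$ciLow > 0] == "left"))
  expect_true(all(d$category[d$ciHigh < 0] == "right"))
  expect_true(all(d$ciLow <= d$liMean & d$liMean <= d$ciHigh))
})
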
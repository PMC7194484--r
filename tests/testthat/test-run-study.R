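test_that("an end-to-end run on a chance-only phenotype reports a2 near zero", {
  out <- tempfile()
  cfg <- runConfig(out, seed = 71,
                   simulateTwins = list(
                     li = list(nMZ = 120, nDZ = 120, a2 = 0),
                     ehi = list(nMZ = 120, nDZ = 120, a2 = 0.4,
                                marginal = "jshape")),
                   power = list(nGrid = c(100, 200), mzFraction = 0.5,
                                a2Values = 0.25, alpha = 0.05),
                   extremes = list(li = list(cutoff = 0, direction = "below")))
  res <- suppressMessages(runStudy(cfg))
  her <- read.csv(file.path(out, "heritability.csv"))
  expect_lt(her$a2[her$measure == "li"], 0.12)
  expect_true(all(file.exists(file.path(out,
    c("double_entry.csv", "heritability.csv", "power.csv", "extremes.csv",
      "summary.json", "effective_config.yaml", "log.txt")))))
  # power table matches the direct computation
  pw <- read.csv(file.path(out, "power.csv"))
  expect_equal(pw$power[pw$n == 200], powerAE(100, 100, 0.25)@power,
               tolerance = 1e-10)
  unlink(out, recursive = TRUE)
})

test_that("re-running with an identical config byte-reproduces the outputs", {
  mkrun <- function(out) {
    cfg <- runConfig(out, seed = 72,
                     simulateTwins = list(y = list(nMZ = 80, nDZ = 80,
                                                   a2 = 0.3)),
                     power = NULL,
                     extremes = list(y = list(cutoff = -0.5,
                                              direction = "below")))
    suppressMessages(runStudy(cfg))
  }
  o1 <- tempfile(); o2 <- tempfile()
  mkrun(o1); mkrun(o2)
  for (f in c("double_entry.csv", "heritability.csv", "extremes.csv",
              "summary.json")) {
    expect_identical(readLines(file.path(o1, f)),
                     readLines(file.path(o2, f)), info = f)
  }
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("stage failures abort with the stage name", {
  out <- tempfile()
  cfg <- runConfig(out, seed = 73,
                   simulateTwins = list(y = list(nMZ = 40, nDZ = 40, a2 = 0)),
                   power = NULL,
                   extremes = list(y = list(cutoff = -50,
                                            direction = "below")))
  expect_error(suppressMessages(runStudy(cfg)), "extremes:y")
  unlink(out, recursive = TRUE)
})

test_that("a recordings-based run produces subject summaries and pair fits", {
  dir <- tempfile(); dir.create(dir)
  n <- 8
  ids <- sprintf("s%02d", 1:n)
  for (i in seq_len(n)) {
    delta <- c(2, 2.5, 1.5, 3, 2, 1, 2.2, 2.8)[i]
    writeVelocityRecording(
      simulateDopplerSession(dopplerSimConfig(nTrials = 13, noiseSd = 0.3,
                                              responseDelta = delta,
                                              seed = 700 + i)),
      file.path(dir, paste0(ids[i], ".csv")))
  }
  fam <- data.frame(familyId = paste0("f", 1:4),
                    zygosity = c("MZ", "MZ", "DZ", "DZ"),
                    subjectId1 = ids[c(1, 3, 5, 7)],
                    subjectId2 = ids[c(2, 4, 6, 8)])
  famFile <- tempfile(fileext = ".csv")
  write.csv(fam, famFile, row.names = FALSE)
  out <- tempfile()
  cfg <- runConfig(out, seed = 74, recordingsDir = dir,
                   familiesFile = famFile, models = character(0),
                   power = NULL)
  res <- suppressMessages(runStudy(cfg))
  subj <- read.csv(file.path(out, "subjects.csv"))
  expect_equal(nrow(subj), n)
  expect_true(all(subj$nAccepted >= 12))
  expect_true(all(abs(subj$liMean - c(2, 2.5, 1.5, 3, 2, 1, 2.2, 2.8)) < 0.8))
  expect_true(file.exists(file.path(out, "trial_lis.csv")))
  expect_equal(length(res$pairs), 4)
  unlink(c(dir, out), recursive = TRUE); unlink(famFile)
})
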
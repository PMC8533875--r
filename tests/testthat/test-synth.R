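test_that("cohort dimensions follow the spec arithmetic", {
  spec <- cohortSpec(nSubjects = 2, nDays = 2, trialsPerTask = 2, seed = 7)
  sessions <- generateCohort(spec)
  expect_length(sessions, 4L)
  for (s in sessions) {
    ev <- events(s)
    expect_equal(nrow(ev), 4L)  # 2 performed + 2 imagined
    expect_equal(sum(ev$task == "performed"), 2L)
    expect_equal(sum(ev$arm == "left"), 2L)
  }
  expect_equal(channelNames(sessions[[1]]),
               c("Fz", "C3", "Cz", "C4", "Pz", "PO7", "Oz", "PO8"))
})

test_that("invalid cohort specs are rejected with the field name", {
  expect_error(cohortSpec(trialsPerTask = 3), "trialsPerTask")
  expect_error(cohortSpec(nSubjects = 0), "nSubjects")
  expect_error(cohortSpec(samplingRate = 80), "samplingRate")
  expect_error(cohortSpec(erdDepth = 1.2), "erdDepth")
})

test_that("same seed gives a bit-identical cohort, different seed differs", {
  spec <- cohortSpec(nSubjects = 2, nDays = 1, trialsPerTask = 2, seed = 13)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(lapply(a, eegSamples), lapply(b, eegSamples))
  expect_identical(lapply(a, events), lapply(b, events))
  spec2 <- cohortSpec(nSubjects = 2, nDays = 1, trialsPerTask = 2, seed = 14)
  c <- generateCohort(spec2)
  expect_false(identical(eegSamples(a[[1]]), eegSamples(c[[1]])))
})

test_that("subject fingerprints are positive, seeded, and subject-specific", {
  spec <- cohortSpec(seed = 5)
  f1 <- subjectFingerprint(spec, 1)
  f1b <- subjectFingerprint(spec, 1)
  f2 <- subjectFingerprint(spec, 2)
  expect_identical(f1, f1b)
  expect_true(all(f1$band_gains > 0))
  expect_false(identical(f1$band_gains, f2$band_gains))
  expect_equal(dim(f1$band_gains), c(8L, 5L))
})

test_that("day effect mixing rows sum to 1 with bounded leakage", {
  spec <- cohortSpec(seed = 3, dayLeakage = 0.05)
  de <- dayEffect(spec, 1, 2)
  expect_equal(rowSums(de$mixing), rep(1, 8))
  offDiag <- de$mixing - diag(diag(de$mixing))
  expect_true(all(rowSums(offDiag) <= 0.05 + 1e-12))
  expect_true(all(de$gain_jitter > 0))
})

test_that("ERD suppresses contralateral mu power by the configured depth", {
  # right-arm task epochs vs left-arm task epochs on C3 (untouched for
  # left-arm trials): band-power ratio ~ 1 - erdDepth, Welch-PSD oracle
  spec <- cohortSpec(nSubjects = 1, nDays = 1, trialsPerTask = 100,
                     erdDepth = 0.4, bandGainDispersion = 0,
                     dayLeakage = 0, dayGainSd = 0, dayNoiseSd = 0,
                     cueS = 0.5, restS = 1, seed = 21)
  sess <- generateCohort(spec)[[1]]
  ev <- events(sess)
  ev <- ev[ev$task == "performed", ]
  c3 <- eegSamples(sess)[match("C3", channelNames(sess)), ]
  win <- round(3 * samplingRate(sess))
  muPow <- function(rows) {
    mean(vapply(rows, function(o)
      welchBandPower(c3[o:(o + win - 1)], samplingRate(sess), 7, 11),
      numeric(1)))
  }
  ratio <- muPow(ev$onset_sample[ev$arm == "right"]) /
    muPow(ev$onset_sample[ev$arm == "left"])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 0.7)
})

test_that("generated signal is band-limited below 50 Hz (alias-safe)", {
  spec <- cohortSpec(nSubjects = 1, nDays = 1, trialsPerTask = 2, seed = 9)
  sess <- generateCohort(spec)[[1]]
  x <- eegSamples(sess)
  fs <- samplingRate(sess)
  for (ch in c(1, 4, 8)) {
    p <- Mod(fft(x[ch, ]))^2
    f <- (seq_along(p) - 1) * fs / length(p)
    f <- pmin(f, fs - f)
    highFrac <- sum(p[f > 50]) / sum(p)
    expect_lt(highFrac, 1e-6)
  }
})

test_that("session CSV round trip is lossless to the written precision", {
  spec <- cohortSpec(nSubjects = 1, nDays = 1, trialsPerTask = 2, seed = 31)
  sess <- generateCohort(spec)[[1]]
  path <- tempfile(fileext = ".csv")
  writeSessionCsv(sess, path)
  back <- readSessionCsv(path, epochS = 3)
  expect_identical(subjectId(back), subjectId(sess))
  expect_identical(dayIndex(back), dayIndex(sess))
  expect_identical(channelNames(back), channelNames(sess))
  expect_equal(samplingRate(back), samplingRate(sess))
  expect_identical(events(back), events(sess))
  expect_equal(eegSamples(back), eegSamples(sess),
               tolerance = 2e-6, ignore_attr = TRUE)
  # serialization determinism: writing the same session twice is
  # byte-identical
  path2 <- tempfile(fileext = ".csv")
  writeSessionCsv(sess, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("malformed session files give parse errors with location", {
  spec <- cohortSpec(nSubjects = 1, nDays = 1, trialsPerTask = 2, seed = 32)
  sess <- generateCohort(spec)[[1]]
  path <- tempfile(fileext = ".csv")
  writeSessionCsv(sess, path)

  # event onset beyond the recording end
  evPath <- sub("\\.csv$", "_events.csv", path)
  ev <- utils::read.csv(evPath)
  ev$onset_sample[1] <- ncol(eegSamples(sess)) + 1000L
  utils::write.csv(ev, evPath, row.names = FALSE, quote = FALSE)
  expect_error(readSessionCsv(path), "outside recording")

  # broken header
  lines <- readLines(path)
  lines[1] <- "subject=S01"
  bad <- tempfile(fileext = ".csv")
  writeLines(lines, bad)
  file.copy(evPath, sub("\\.csv$", "_events.csv", bad))
  expect_error(readSessionCsv(bad), "line 1")
})

test_that("a session with no events is valid and yields no epochs", {
  spec <- cohortSpec(nSubjects = 1, nDays = 1, trialsPerTask = 2, seed = 33)
  sess <- generateCohort(spec)[[1]]
  empty <- new("RawSession",
               subjectId = subjectId(sess), dayIndex = dayIndex(sess),
               samples = eegSamples(sess),
               samplingRate = samplingRate(sess),
               channelNames = channelNames(sess), epochS = 3,
               events = events(sess)[0, ])
  path <- tempfile(fileext = ".csv")
  writeSessionCsv(empty, path)
  back <- readSessionCsv(path)
  expect_equal(nrow(events(back)), 0L)
  expect_length(extractEpochs(back), 0L)
})

test_that("stronger fingerprint dispersion improves authentication", {
  # the subject-separability dial: downstream accuracy is non-decreasing
  # in the band-gain dispersion (3 levels x 2 seeds, tiny cohort)
  accAt <- function(disp, seed) {
    spec <- cohortSpec(nSubjects = 3, nDays = 2, trialsPerTask = 4,
                       bandGainDispersion = disp, seed = seed)
    pool <- buildFeaturePool(generateCohort(spec))
    cfg <- ensembleConfig(M = 1, base = tinyLearnerConfig(seed), seed = seed)
    rep <- leaveOneDayOut(pool, authPolicy(list(authTask("performed", "left"))),
                          cfg)
    mean(rep$results$accuracy)
  }
  acc <- vapply(c(0.02, 0.2, 0.8),
                function(d) mean(c(accAt(d, 1), accAt(d, 2))), numeric(1))
  expect_true(all(diff(acc) >= -1e-9))
})
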
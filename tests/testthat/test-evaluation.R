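test_that("confusion metrics follow the standard biometric definitions", {
  m <- confusionMetrics(tp = 9, fn = 1, tn = 18, fp = 2)
  expect_equal(m$frr, 0.1)
  expect_equal(m$far, 0.1)
  expect_equal(m$accuracy, 0.9)
  expect_equal(confusionMetrics(10, 0, 20, 0),
               list(accuracy = 1, far = 0, frr = 0))
  allReject <- confusionMetrics(0, 10, 20, 0)
  expect_equal(allReject$far, 0)
  expect_equal(allReject$frr, 1)
  expect_error(confusionMetrics(0, 0, 5, 5), "genuine")
  expect_error(confusionMetrics(5, 5, 0, 0), "imposter")
})

test_that("leave-one-day-out folds are day-disjoint and complete", {
  pool <- smallPool()
  cfg <- ensembleConfig(M = 1, base = tinyLearnerConfig(epochs = 4L), seed = 3)
  pol <- authPolicy(list(authTask("performed", "left"),
                         authTask("performed", "right")))
  rep <- leaveOneDayOut(pool, pol, cfg)
  r <- rep$results

  expect_setequal(unique(r$fold), c(1L, 2L))
  expect_setequal(unique(r$scheme),
                  c("performed-left", "performed-right", "combined"))
  # one row per subject x scheme x fold
  expect_equal(nrow(r), 4 * 3 * 2)
  # training days never contain the test fold
  for (i in seq_len(nrow(r)))
    expect_false(as.character(r$fold[i]) %in%
                   strsplit(r$train_days[i], ",")[[1]])
  # test attempts on fold d come only from the held-out day's epochs:
  # attempt counts match the day's epoch counts
  att <- rep$attempts
  perFold <- table(att$fold[att$scheme == "performed-left" &
                              att$subject == "S01"])
  m <- pool$meta
  for (d in c(1L, 2L))
    expect_equal(unname(perFold[as.character(d)]),
                 sum(m$day == d & m$task == "performed" & m$arm == "left"))

  # metric algebra: every row's metrics reproduce from its counts
  for (i in seq_len(nrow(r))) {
    m2 <- confusionMetrics(r$TP[i], r$FN[i], r$TN[i], r$FP[i])
    expect_equal(r$accuracy[i], m2$accuracy)
    expect_equal(r$FAR[i], m2$far)
    expect_equal(r$FRR[i], m2$frr)
  }

  # aggregates equal an independent re-aggregation
  for (sc in unique(r$scheme)) {
    expect_equal(rep$aggregates$accuracy[rep$aggregates$scheme == sc],
                 mean(r$accuracy[r$scheme == sc]))
  }
})

test_that("conjunction algebra binds the combined scheme exactly", {
  pool <- smallPool()
  cfg <- ensembleConfig(M = 1, base = tinyLearnerConfig(epochs = 4L), seed = 3)
  pol <- authPolicy(list(authTask("performed", "left"),
                         authTask("performed", "right")))
  rep <- leaveOneDayOut(pool, pol, cfg)
  r <- rep$results
  for (s in unique(r$subject)) for (d in unique(r$fold)) {
    far <- function(sc) r$FAR[r$subject == s & r$fold == d & r$scheme == sc]
    frr <- function(sc) r$FRR[r$subject == s & r$fold == d & r$scheme == sc]
    comps <- c("performed-left", "performed-right")
    expect_lte(far("combined"), min(vapply(comps, far, numeric(1))) + 1e-12)
    expect_gte(frr("combined"), max(vapply(comps, frr, numeric(1))) - 1e-12)
  }
})

test_that("evaluation requires complete day coverage", {
  pool <- smallPool()
  broken <- pool
  drop <- broken$meta$subject_id == "S02" & broken$meta$day == 2
  broken$meta <- broken$meta[!drop, , drop = FALSE]
  broken$features <- broken$features[which(!drop)]
  expect_error(
    leaveOneDayOut(broken, authPolicy(list(authTask("performed", "left"))),
                   ensembleConfig(M = 1, base = tinyLearnerConfig())),
    "S02 has no epochs on day 2")
})

test_that("evaluation reports round-trip to disk", {
  pool <- smallPool()
  cfg <- ensembleConfig(M = 1, base = tinyLearnerConfig(epochs = 4L), seed = 3)
  rep <- leaveOneDayOut(pool, authPolicy(list(authTask("performed", "left"))),
                        cfg)
  dir <- tempfile()
  files <- writeEvalReport(rep, dir)
  back <- utils::read.csv(files[1])
  expect_equal(nrow(back), nrow(rep$results))
  summ <- jsonlite::read_json(files[2], simplifyVector = TRUE)
  expect_equal(summ$aggregates$accuracy, rep$aggregates$accuracy)
})

test_that("training-fraction sweep shares subsets and is well-formed", {
  pool <- cachedPool("sweep", list(nSubjects = 3, nDays = 2,
                                   trialsPerTask = 10, seed = 41))
  cfg <- ensembleConfig(M = 3, base = tinyLearnerConfig(epochs = 4L), seed = 1)
  sw <- trainingFractionSweep(pool, fractions = c(0.4, 1.0), nRuns = 1,
                              cfg = cfg, baggedM = 3, subjects = "S01",
                              folds = 1, seed = 5)
  expect_setequal(unique(sw$method), c("single_lstm", "bagged"))
  expect_setequal(unique(sw$fraction), c(0.4, 1.0))
  # both methods saw identical subset sizes per cell
  for (f in c(0.4, 1.0))
    expect_equal(unique(sw$n_train[sw$fraction == f]),
                 2 * round(f * 5))
  # deterministic under the sweep seed
  sw2 <- trainingFractionSweep(pool, fractions = c(0.4, 1.0), nRuns = 1,
                               cfg = cfg, baggedM = 3, subjects = "S01",
                               folds = 1, seed = 5)
  expect_identical(sw, sw2)
  expect_warning(
    trainingFractionSweep(pool, fractions = 0.05, nRuns = 1, cfg = cfg,
                          subjects = "S01", folds = 1, seed = 5),
    "skipped")
})

test_that("more training data does not hurt on a separable cohort", {
  pool <- cachedPool("sweep", list(nSubjects = 3, nDays = 2,
                                   trialsPerTask = 10, seed = 41))
  cfg <- ensembleConfig(M = 3, base = tinyLearnerConfig(epochs = 6L), seed = 1)
  accs <- vapply(1:3, function(seed) {
    sw <- trainingFractionSweep(pool, fractions = c(0.2, 1.0), nRuns = 1,
                                cfg = cfg, baggedM = 3, folds = 1,
                                seed = seed)
    c(mean(sw$accuracy[sw$fraction == 0.2]),
      mean(sw$accuracy[sw$fraction == 1.0]))
  }, numeric(2))
  expect_gte(mean(accs[2, ]), mean(accs[1, ]))
})

test_that("bagging-size sweep emits one row per M per subject", {
  pool <- smallPool()
  cfg <- ensembleConfig(base = tinyLearnerConfig(epochs = 4L), seed = 2)
  sw <- baggingSizeSweep(pool, sizes = c(1L, 3L), cfg = cfg,
                         policy = authPolicy(list(authTask("performed",
                                                           "left"))))
  expect_equal(nrow(sw), 2 * 4)
  expect_true(all(table(sw$M) == 4))
  sw2 <- baggingSizeSweep(pool, sizes = c(1L, 3L), cfg = cfg,
                          policy = authPolicy(list(authTask("performed",
                                                            "left"))))
  expect_identical(sw, sw2)
})

test_that("signed-rank test matches the exact enumeration example", {
  b <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  a <- b + 1
  w <- wilcoxonSignedRank(a, b)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 2 / 2^10)
  expect_equal(w$method, "exact")
})

test_that("signed-rank agrees with the stats reference implementation", {
  set.seed(7)
  # tie-free exact case
  d <- sample(c(-1, 1), 10, TRUE) * (1:10 + runif(10, 0, 0.3))
  a <- rnorm(10); b <- a - d
  mine <- wilcoxonSignedRank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(mine$p_value, unname(ref$p.value))
  # large-n normal approximation
  set.seed(8)
  a2 <- rnorm(30); b2 <- rnorm(30, 0.3)
  mine2 <- wilcoxonSignedRank(a2, b2)
  ref2 <- stats::wilcox.test(a2, b2, paired = TRUE, exact = FALSE,
                             correct = FALSE)
  expect_equal(mine2$p_value, unname(ref2$p.value), tolerance = 1e-10)
  expect_equal(mine2$method, "normal_approx")
})

test_that("signed-rank p-values are roughly uniform under the null", {
  set.seed(9)
  ps <- vapply(1:200, function(i) {
    a <- rnorm(16); b <- rnorm(16)
    wilcoxonSignedRank(a, b)$p_value
  }, numeric(1))
  # discrete ranks can tie p-values; the KS here is only a sanity check
  ksP <- suppressWarnings(stats::ks.test(ps, "punif")$p.value)
  expect_gt(ksP, 0.01)
})

test_that("degenerate signed-rank inputs error", {
  expect_error(wilcoxonSignedRank(1:5, 1:5), "degenerate")
  expect_error(wilcoxonSignedRank(c(1, 2, 3, 4, 9), c(1, 1, 1, 1, 9)),
               ">= 5 non-zero")
  expect_error(wilcoxonSignedRank(1:4, 2:5), ">= 5")
  expect_error(wilcoxonSignedRank(1:3, 1:2), "equal length")
})
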
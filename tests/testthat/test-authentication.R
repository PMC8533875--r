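# a cheap hand-built pool: many subjects, one tiny random feature matrix
# per (subject, day, task, arm, trial); enough structure for the
# balanced-sampling and scenario plumbing without any real signal
fakePool <- function(nSubjects, nDays = 1L, trials = 2L, d = 4L, nT = 6L,
                     seed = 1L) {
  set.seed(seed)
  rows <- list(); feats <- list()
  for (s in seq_len(nSubjects)) for (day in seq_len(nDays))
    for (task in c("performed", "imagined")) for (arm in c("left", "right"))
      for (tr in seq_len(trials)) {
        feats[[length(feats) + 1L]] <- matrix(rnorm(d * nT, mean = s), d, nT)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%02d", s), day = day, task = task,
          arm = arm, trial = tr, stringsAsFactors = FALSE)
      }
  pool <- list(meta = do.call(rbind, rows), features = feats)
  class(pool) <- c("FeaturePool", "list")
  pool
}

test_that("training sets are balanced with equal negatives", {
  pool <- smallPool()
  ts <- buildTrainingSet(pool, "S01", "performed", "left",
                         c("S02", "S03", "S04"), seed = 5)
  nPos <- sum(ts$labels == 1)
  expect_equal(sum(ts$labels == 0), nPos)
  expect_true(all(ts$meta$subject_id[ts$labels == 1] == "S01"))
  expect_true(all(ts$meta$subject_id[ts$labels == 0] %in%
                    c("S02", "S03", "S04")))
  expect_true(all(ts$meta$task == "performed" & ts$meta$arm == "left"))
  # seeded selection is reproducible
  ts2 <- buildTrainingSet(pool, "S01", "performed", "left",
                          c("S02", "S03", "S04"), seed = 5)
  expect_identical(ts$meta, ts2$meta)
  expect_error(buildTrainingSet(pool, "S01", "performed", "left",
                                character(0)), "imposter")
})

test_that("scarce imposter epochs trigger replacement with a warning", {
  pool <- fakePool(2, trials = 4L)
  # restrict the imposter to fewer epochs than positives
  keep <- !(pool$meta$subject_id == "S02" & pool$meta$trial > 1)
  pool2 <- list(meta = pool$meta[keep, , drop = FALSE],
                features = pool$features[which(keep)])
  class(pool2) <- class(pool)
  expect_warning(
    ts <- buildTrainingSet(pool2, "S01", "performed", "left", "S02", 3),
    "replacement")
  expect_equal(sum(ts$labels == 0), sum(ts$labels == 1))
})

test_that("imposter pools match the two authentication scenarios", {
  pool <- fakePool(15)
  cfg <- ensembleConfig(M = 1, base = tinyLearnerConfig(epochs = 2L,
                                                        hiddenUnits = 4L),
                        seed = 3)
  pol <- authPolicy(list(authTask("performed", "left")))

  known <- fitSubjectModel(pool, "S01", pol, "known_imposters", cfg)
  expect_length(known@imposterPool, 14L)  # 15 - 1

  group1 <- sprintf("S%02d", 1:10)
  unseen <- fitSubjectModel(pool, "S01", pol, "unseen_imposters", cfg,
                            trainingGroup = group1)
  expect_length(unseen@imposterPool, 9L)  # 10 - 1
  expect_false(any(sprintf("S%02d", 11:15) %in% unseen@imposterPool))
  expect_error(fitSubjectModel(pool, "S01", pol, "unseen_imposters", cfg),
               "trainingGroup")
})

test_that("held-out subjects never contribute training epochs", {
  pool <- fakePool(6)
  group1 <- sprintf("S%02d", 1:4)
  ts <- buildTrainingSet(pool, "S01", "performed", "left",
                         setdiff(group1, "S01"), seed = 2)
  expect_true(all(ts$meta$subject_id %in% group1))
})

test_that("a model covers every policy task with its own ensemble", {
  pool <- fakePool(3)
  cfg <- ensembleConfig(M = 1, base = tinyLearnerConfig(epochs = 2L,
                                                        hiddenUnits = 4L),
                        seed = 1)
  pol <- authPolicy(list(authTask("performed", "left"),
                         authTask("performed", "right"),
                         authTask("imagined", "left"),
                         authTask("imagined", "right")))
  model <- fitSubjectModel(pool, "S02", pol, "known_imposters", cfg)
  expect_setequal(names(model@authenticators),
                  c("performed-left", "performed-right",
                    "imagined-left", "imagined-right"))
})

test_that("authentication is the conjunction of per-task votes", {
  mkModel <- function(dec1, dec2) {
    new("SubjectModel", subjectId = "S01",
        authenticators = list(
          "performed-left" = constEnsemble(rep(dec1, 3)),
          "performed-right" = constEnsemble(rep(dec2, 3))),
        scenario = "known_imposters", imposterPool = "S02",
        policy = unclass(authPolicy(list(authTask("performed", "left"),
                                         authTask("performed", "right")))))
  }
  att <- list("performed-left" = matrix(0, 3, 5),
              "performed-right" = matrix(0, 3, 5))
  expect_equal(authenticate(mkModel(1L, 1L), att)$decision, 1L)
  expect_equal(authenticate(mkModel(1L, 0L), att)$decision, 0L)
  expect_equal(authenticate(mkModel(0L, 0L), att)$decision, 0L)
  expect_error(authenticate(mkModel(1L, 1L),
                            att["performed-left"]), "missing")

  single <- new("SubjectModel", subjectId = "S01",
                authenticators = list("performed-left" = constEnsemble(1L)),
                scenario = "known_imposters", imposterPool = "S02",
                policy = unclass(authPolicy(list(authTask("performed",
                                                          "left")))))
  res <- authenticate(single, att)
  expect_equal(res$decision,
               vote(single@authenticators[[1]],
                    att[["performed-left"]])$decision)
})

test_that("policies validate their tasks", {
  expect_error(authPolicy(list()), "at least one")
  expect_error(authPolicy(list(authTask("performed", "left"),
                               authTask("performed", "left"))), "unique")
  expect_error(authTask("walking", "left"))
})
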
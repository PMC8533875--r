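#' Task identifiers and policies
#'
#' `authTask()` names one (task, arm) paradigm; `taskKey()` is its
#' canonical string form `"task-arm"`. `authPolicy()` bundles the tasks
#' an attempt must complete; under the `"all_accept"` rule the attempt is
#' accepted only if every task's authenticator votes Yes (conjunction),
#' which trades a lower FAR against a higher FRR as tasks are added.
#'
#' @param task `"performed"` or `"imagined"`.
#' @param arm `"left"` or `"right"`.
#' @return `authTask()`: list `(task, arm)`; `taskKey()`: character.
#' @export
authTask <- function(task = c("performed", "imagined"),
                     arm = c("left", "right")) {
  list(task = match.arg(task), arm = match.arg(arm))
}

#' @rdname authTask
#' @export
taskKey <- function(task, arm) paste(task, arm, sep = "-")

#' @rdname authTask
#' @param tasks non-empty list of [authTask()] (unique).
#' @param rule decision combination rule across tasks.
#' @export
authPolicy <- function(tasks = list(authTask("performed", "left")),
                       rule = c("all_accept")) {
  rule <- match.arg(rule)
  if (!length(tasks)) stop("policy must contain at least one task", call. = FALSE)
  keys <- vapply(tasks, function(t) taskKey(t$task, t$arm), character(1))
  if (anyDuplicated(keys)) stop("policy tasks must be unique", call. = FALSE)
  pol <- list(tasks = tasks, rule = rule)
  class(pol) <- c("AuthPolicy", "list")
  pol
}

#' Compute a feature pool from raw sessions
#'
#' Runs preprocess (filter, resample, epoch) and feature assembly over a
#' list of sessions and collects the per-trial feature matrices with
#' their provenance (subject, day, task, arm, within-condition trial
#' index).
#'
#' @param sessions list of [RawSession-class].
#' @param pcfg a [preprocessConfig()].
#' @param cfg a [stftConfig()].
#' @param scheme a [subbandScheme()].
#' @param mode feature channel mode, see [assembleFeatures()].
#' @return a `FeaturePool`: list with `meta` (data.frame) and `features`
#'   (list of [FeatureMatrix-class]).
#' @export
buildFeaturePool <- function(sessions, pcfg = preprocessConfig(),
                             cfg = stftConfig(), scheme = subbandScheme(),
                             mode = c("all_channels", "paper_literal")) {
  mode <- match.arg(mode)
  feats <- list(); rows <- list()
  for (s in sessions) {
    eps <- extractEpochs(s, pcfg)
    counter <- new.env()
    for (ep in eps) {
      key <- taskKey(ep@task, ep@arm)
      k <- (get0(key, envir = counter, ifnotfound = 0L)) + 1L
      assign(key, k, envir = counter)
      feats[[length(feats) + 1L]] <- assembleFeatures(ep, cfg, scheme, mode)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ep@subjectId, day = ep@dayIndex,
        task = ep@task, arm = ep@arm, trial = k,
        stringsAsFactors = FALSE)
    }
  }
  pool <- list(meta = do.call(rbind, rows), features = feats)
  class(pool) <- c("FeaturePool", "list")
  pool
}

poolSubset <- function(pool, keep) {
  out <- list(meta = pool$meta[keep, , drop = FALSE],
              features = pool$features[which(keep)])
  class(out) <- class(pool)
  out
}

#' Build a balanced per-subject training set
#'
#' Positives are all of the subject's pool epochs for the given (task,
#' arm); negatives are an equal number of imposter epochs of the same
#' (task, arm), sampled uniformly without replacement from
#' `imposterPool` subjects (with replacement, with a warning, if the
#' imposters have fewer epochs than needed). Selection is seeded and
#' reproducible.
#'
#' @param pool a [buildFeaturePool()] result (already restricted to
#'   training days by the caller).
#' @param subjectId authorized subject.
#' @param task,arm the paradigm.
#' @param imposterPool character vector of imposter subject ids.
#' @param seed integer seed for negative sampling.
#' @return a [labeledSet()] with provenance `meta`.
#' @export
buildTrainingSet <- function(pool, subjectId, task, arm, imposterPool,
                             seed = 1L) {
  m <- pool$meta
  posIdx <- which(m$subject_id == subjectId & m$task == task & m$arm == arm)
  if (!length(posIdx))
    stop(sprintf("no positive epochs for subject %s, %s", subjectId,
                 taskKey(task, arm)), call. = FALSE)
  negPool <- which(m$subject_id %in% imposterPool & m$task == task &
                     m$arm == arm)
  if (!length(imposterPool) || !length(negPool))
    stop("empty imposter pool", call. = FALSE)
  nPos <- length(posIdx)
  set.seed(seed)
  if (length(negPool) >= nPos) {
    negIdx <- negPool[sample.int(length(negPool), nPos)]
  } else {
    warning(sprintf(
      "imposter pool has %d epochs < %d positives; sampling with replacement",
      length(negPool), nPos), call. = FALSE)
    negIdx <- negPool[sample.int(length(negPool), nPos, replace = TRUE)]
  }
  idx <- c(posIdx, negIdx)
  labeledSet(pool$features[idx],
             rep(c(1L, 0L), c(nPos, nPos)),
             meta = m[idx, , drop = FALSE])
}

#' Enroll a subject: fit one ensemble per policy task
#'
#' Under `scenario = "known_imposters"` the negatives come from every
#' other subject in the pool (14 others in the default 15-subject
#' cohort). Under `scenario = "unseen_imposters"` the negatives come only
#' from `trainingGroup` minus the subject (9 others in the default 10/5
#' split); held-out subjects never contribute training epochs.
#'
#' @param pool a training-day [buildFeaturePool()].
#' @param subjectId subject to enroll.
#' @param policy an [authPolicy()].
#' @param scenario imposter scenario.
#' @param cfg an [ensembleConfig()]; per-task seeds are derived from it.
#' @param trainingGroup subject ids available for training negatives
#'   (required for `"unseen_imposters"`).
#' @return a [SubjectModel-class].
#' @export
fitSubjectModel <- function(pool, subjectId, policy = authPolicy(),
                            scenario = c("known_imposters",
                                         "unseen_imposters"),
                            cfg = ensembleConfig(),
                            trainingGroup = NULL) {
  scenario <- match.arg(scenario)
  allSubjects <- unique(pool$meta$subject_id)
  imposters <- switch(scenario,
    known_imposters = setdiff(allSubjects, subjectId),
    unseen_imposters = {
      if (is.null(trainingGroup))
        stop("scenario 'unseen_imposters' requires trainingGroup", call. = FALSE)
      setdiff(trainingGroup, subjectId)
    })
  if (!length(imposters)) stop("empty imposter pool", call. = FALSE)
  trainPool <- if (scenario == "unseen_imposters") {
    poolSubset(pool, pool$meta$subject_id %in% c(subjectId, imposters))
  } else pool
  auths <- list()
  for (tk in policy$tasks) {
    key <- taskKey(tk$task, tk$arm)
    ts <- buildTrainingSet(trainPool, subjectId, tk$task, tk$arm,
                           imposters, seed = mixSeed(cfg$seed, 31L,
                                                     match(key, c(
                                                       "performed-left",
                                                       "performed-right",
                                                       "imagined-left",
                                                       "imagined-right"))))
    ecfg <- cfg
    ecfg$seed <- mixSeed(cfg$seed, 32L, match(key, c(
      "performed-left", "performed-right", "imagined-left",
      "imagined-right")))
    auths[[key]] <- trainEnsemble(ts, ecfg,
                                  context = list(subject_id = subjectId,
                                                 task = tk$task,
                                                 arm = tk$arm))
  }
  new("SubjectModel",
      subjectId = subjectId, authenticators = auths,
      scenario = scenario, imposterPool = imposters,
      policy = unclass(policy))
}

#' Authenticate an attempt against a subject model
#'
#' The attempt must supply one feature matrix per policy task (named by
#' [taskKey()]). Each task's ensemble votes; under the `"all_accept"`
#' rule the final decision is 1 iff every per-task decision is 1.
#'
#' @param model a [SubjectModel-class].
#' @param attempt named list mapping task keys to
#'   [FeatureMatrix-class]/matrix.
#' @return list with `decision` (0/1) and `per_task` (named integer
#'   vector of per-task decisions).
#' @export
authenticate <- function(model, attempt) {
  stopifnot(is(model, "SubjectModel"))
  keys <- names(model@authenticators)
  missing <- setdiff(keys, names(attempt))
  if (length(missing))
    stop(sprintf("attempt is missing features for task(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  perTask <- vapply(keys, function(k)
    vote(model@authenticators[[k]], attempt[[k]])$decision, integer(1))
  names(perTask) <- keys
  list(decision = as.integer(all(perTask == 1L)), per_task = perTask)
}
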
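#' Biometric verification metrics from confusion counts
#'
#' Standard biometric definitions: FAR = FP / (FP + TN) over imposter
#' attempts, FRR = FN / (FN + TP) over genuine attempts, accuracy =
#' (TP + TN) / all attempts. TP counts genuine attempts accepted, FN
#' genuine rejected, TN imposter rejected, FP imposter accepted.
#'
#' @param tp,fn,tn,fp non-negative counts.
#' @return list with `accuracy`, `far`, `frr`.
#' @export
confusionMetrics <- function(tp, fn, tn, fp) {
  if (any(c(tp, fn, tn, fp) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (tp + fn == 0)
    stop("undefined metric: no genuine attempts (TP + FN = 0)", call. = FALSE)
  if (tn + fp == 0)
    stop("undefined metric: no imposter attempts (TN + FP = 0)", call. = FALSE)
  list(accuracy = (tp + tn) / (tp + fn + tn + fp),
       far = fp / (fp + tn),
       frr = fn / (fn + tp))
}

# decide every test epoch of one (task, arm) with one ensemble;
# returns data.frame of per-attempt decisions with provenance
decideEpochs <- function(ens, pool, idx) {
  if (!length(idx)) return(NULL)
  m <- pool$meta[idx, , drop = FALSE]
  data.frame(
    attempt_subject = m$subject_id, trial = m$trial,
    decision = vapply(idx, function(i)
      vote(ens, pool$features[[i]])$decision, integer(1)),
    stringsAsFactors = FALSE)
}

#' Leave-one-day-out cross-validated authentication evaluation
#'
#' For each fold day *d*, models are trained on the epochs of all other
#' days and tested on day *d*: genuine attempts are the enrolled
#' subject's day-*d* epochs; imposter attempts are every other subject's
#' day-*d* epochs, per (task, arm). Single-task schemes are evaluated per
#' policy task; when the policy has more than one task a `"combined"`
#' scheme is added in which attempts pair same-trial-index epochs across
#' tasks and the decision is the conjunction of the per-task votes.
#'
#' @param pool a [buildFeaturePool()] over all days.
#' @param policy an [authPolicy()].
#' @param cfg an [ensembleConfig()]; per-(fold, subject) seeds derive
#'   from `cfg$seed`.
#' @param subjects subjects to enroll (default: all in the pool).
#' @param scenario,trainingGroup see [fitSubjectModel()].
#' @param alpha significance level for the pairwise scheme comparisons.
#' @return an `EvalReport`: list with `results` (one row per subject x
#'   scheme x fold: TP/FN/TN/FP + accuracy/FAR/FRR), `attempts`
#'   (per-attempt decisions incl. per-task votes), `aggregates` (means
#'   over subjects and folds per scheme), `significance` (pairwise
#'   Wilcoxon signed-rank over per-subject means, when >= 2 schemes and
#'   >= 5 subjects), `alpha`.
#' @export
leaveOneDayOut <- function(pool, policy = authPolicy(),
                           cfg = ensembleConfig(), subjects = NULL,
                           scenario = c("known_imposters",
                                        "unseen_imposters"),
                           trainingGroup = NULL, alpha = 0.05) {
  scenario <- match.arg(scenario)
  m <- pool$meta
  days <- sort(unique(m$day))
  if (is.null(subjects)) subjects <- sort(unique(m$subject_id))
  for (s in subjects) for (d in days)
    if (!any(m$subject_id == s & m$day == d))
      stop(sprintf("subject %s has no epochs on day %d", s, d), call. = FALSE)

  keys <- vapply(policy$tasks, function(t) taskKey(t$task, t$arm),
                 character(1))
  combined <- length(keys) > 1L
  resRows <- list(); attRows <- list()

  for (d in days) {
    trainPool <- poolSubset(pool, m$day != d)
    testPool <- poolSubset(pool, m$day == d)
    tm <- testPool$meta
    trainDays <- paste(sort(unique(trainPool$meta$day)), collapse = ",")
    for (si in seq_along(subjects)) {
      s <- subjects[si]
      ecfg <- cfg
      ecfg$seed <- mixSeed(cfg$seed, 41L, which(days == d), si)
      model <- fitSubjectModel(trainPool, s, policy, scenario, ecfg,
                               trainingGroup = trainingGroup)
      perTask <- list()
      for (k in keys) {
        tk <- policy$tasks[[match(k, keys)]]
        idx <- which(tm$task == tk$task & tm$arm == tk$arm)
        dec <- decideEpochs(model@authenticators[[k]], testPool, idx)
        dec$genuine <- dec$attempt_subject == s
        perTask[[k]] <- dec
        tp <- sum(dec$genuine & dec$decision == 1L)
        fn <- sum(dec$genuine & dec$decision == 0L)
        fp <- sum(!dec$genuine & dec$decision == 1L)
        tn <- sum(!dec$genuine & dec$decision == 0L)
        met <- confusionMetrics(tp, fn, tn, fp)
        resRows[[length(resRows) + 1L]] <- data.frame(
          subject = s, scheme = k, fold = d, train_days = trainDays,
          TP = tp, FN = fn, TN = tn, FP = fp, accuracy = met$accuracy,
          FAR = met$far, FRR = met$frr, stringsAsFactors = FALSE)
        attRows[[length(attRows) + 1L]] <- cbind(
          data.frame(subject = s, scheme = k, fold = d,
                     stringsAsFactors = FALSE), dec)
      }
      if (combined) {
        # pair per-task decisions by (attempting subject, trial index)
        base <- perTask[[1]][, c("attempt_subject", "trial", "genuine")]
        base$combined <- perTask[[1]]$decision
        for (k in keys[-1]) {
          other <- perTask[[k]]
          mi <- match(paste(base$attempt_subject, base$trial),
                      paste(other$attempt_subject, other$trial))
          base$combined <- base$combined & !is.na(mi) & other$decision[mi]
        }
        keep <- !is.na(base$combined)
        base <- base[keep, , drop = FALSE]
        dec <- data.frame(attempt_subject = base$attempt_subject,
                          trial = base$trial,
                          decision = as.integer(base$combined),
                          genuine = base$genuine,
                          stringsAsFactors = FALSE)
        tp <- sum(dec$genuine & dec$decision == 1L)
        fn <- sum(dec$genuine & dec$decision == 0L)
        fp <- sum(!dec$genuine & dec$decision == 1L)
        tn <- sum(!dec$genuine & dec$decision == 0L)
        met <- confusionMetrics(tp, fn, tn, fp)
        resRows[[length(resRows) + 1L]] <- data.frame(
          subject = s, scheme = "combined", fold = d,
          train_days = trainDays, TP = tp, FN = fn, TN = tn, FP = fp,
          accuracy = met$accuracy, FAR = met$far, FRR = met$frr,
          stringsAsFactors = FALSE)
        attRows[[length(attRows) + 1L]] <- cbind(
          data.frame(subject = s, scheme = "combined", fold = d,
                     stringsAsFactors = FALSE), dec)
      }
    }
  }

  results <- do.call(rbind, resRows)
  attempts <- do.call(rbind, attRows)
  schemes <- unique(results$scheme)
  aggregates <- do.call(rbind, lapply(schemes, function(sc) {
    r <- results[results$scheme == sc, ]
    data.frame(scheme = sc, accuracy = mean(r$accuracy),
               FAR = mean(r$FAR), FRR = mean(r$FRR),
               stringsAsFactors = FALSE)
  }))

  significance <- NULL
  if (length(schemes) > 1L && length(subjects) >= 5L) {
    bySubj <- function(sc, col) {
      r <- results[results$scheme == sc, ]
      vapply(subjects, function(s) mean(r[[col]][r$subject == s]),
             numeric(1))
    }
    sig <- list()
    for (i in seq_len(length(schemes) - 1L)) for (j in (i + 1L):length(schemes))
      for (col in c("accuracy", "FAR", "FRR")) {
        a <- bySubj(schemes[i], col); b <- bySubj(schemes[j], col)
        w <- tryCatch(wilcoxonSignedRank(a, b),
                      error = function(e) list(statistic = NA_real_,
                                               p_value = NA_real_))
        sig[[length(sig) + 1L]] <- data.frame(
          scheme_a = schemes[i], scheme_b = schemes[j], metric = col,
          statistic = w$statistic, p_value = w$p_value,
          significant = !is.na(w$p_value) & w$p_value < alpha,
          stringsAsFactors = FALSE)
      }
    significance <- do.call(rbind, sig)
  }

  out <- list(results = results, attempts = attempts,
              aggregates = aggregates, significance = significance,
              alpha = alpha, policy = unclass(policy),
              scenario = scenario)
  class(out) <- c("EvalReport", "list")
  out
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: %d subjects, %d folds, scenario %s\n",
              length(unique(x$results$subject)),
              length(unique(x$results$fold)), x$scenario))
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Tidy CSV (one row per subject x scheme x fold, all four confusion
#' counts kept so any metric definition can be recomputed) plus a JSON
#' summary with aggregates and the significance table.
#'
#' @param report an `EvalReport`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "results.csv")
  utils::write.csv(report$results, csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(aggregates = report$aggregates,
         significance = report$significance, alpha = report$alpha,
         scenario = report$scenario),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv, js))
}

#' Training-fraction sweep: single LSTM vs bagging
#'
#' For each run and fold, a stratified random subset containing a given
#' fraction of the aggregated training set is drawn; a single LSTM and a
#' bagged ensemble (size `baggedM`) are trained on the *same* subset and
#' scored on the same fixed test day. Results are averaged over runs and
#' folds downstream.
#'
#' @param pool a [buildFeaturePool()].
#' @param fractions fractions of the aggregated training set in (0, 1].
#' @param nRuns independent subset draws per (fraction, fold).
#' @param task an [authTask()] (single-task evaluation).
#' @param cfg an [ensembleConfig()]; `cfg$base` is the learner
#'   configuration for both methods, `baggedM` the ensemble size of the
#'   bagged method.
#' @param baggedM bagging size for the bagged method.
#' @param subjects,folds restrict enrolled subjects / fold days.
#' @param seed sweep seed (subset selection, shared across methods).
#' @return data.frame: fraction, method, run, subject, fold, n_train,
#'   accuracy, FAR, FRR.
#' @export
trainingFractionSweep <- function(pool, fractions = seq(0.1, 0.9, 0.1),
                                  nRuns = 5L,
                                  task = authTask("performed", "left"),
                                  cfg = ensembleConfig(),
                                  baggedM = 5L, subjects = NULL,
                                  folds = NULL, seed = 1L) {
  stopifnot(all(fractions > 0 & fractions <= 1), nRuns >= 1L)
  m <- pool$meta
  days <- sort(unique(m$day))
  if (!is.null(folds)) days <- days[folds]
  if (is.null(subjects)) subjects <- sort(unique(m$subject_id))
  key <- taskKey(task$task, task$arm)
  rows <- list()
  for (d in days) {
    trainPool <- poolSubset(pool, m$day != d)
    testPool <- poolSubset(pool, m$day == d)
    tidx <- which(testPool$meta$task == task$task &
                    testPool$meta$arm == task$arm)
    for (si in seq_along(subjects)) {
      s <- subjects[si]
      full <- buildTrainingSet(trainPool, s, task$task, task$arm,
                               setdiff(unique(m$subject_id), s),
                               seed = mixSeed(seed, 51L, which(days == d), si))
      for (r in seq_len(nRuns)) for (f in fractions) {
        nPer <- round(f * sum(full$labels == 1L))
        if (nPer < 1L) {
          warning(sprintf("fraction %.2f yields < 1 epoch per class; skipped", f),
                  call. = FALSE)
          next
        }
        set.seed(mixSeed(seed, 52L, which(days == d), si, r,
                         as.integer(round(f * 100))))
        sub <- unlist(lapply(c(1L, 0L), function(cl) {
          ii <- which(full$labels == cl)
          ii[sample.int(length(ii), nPer)]
        }))
        subset <- labeledSet(full$features[sub], full$labels[sub],
                             meta = full$meta[sub, , drop = FALSE])
        runSeed <- mixSeed(seed, 53L, which(days == d), si, r,
                           as.integer(round(f * 100)))
        for (method in c("single_lstm", "bagged")) {
          if (method == "single_lstm") {
            lcfg <- cfg$base
            lcfg$seed <- runSeed
            learner <- trainLearner(subset, lcfg)
            decide <- function(feat) predictLearner(learner, feat)$decision
          } else {
            ecfg <- cfg
            ecfg$M <- as.integer(baggedM)
            ecfg$seed <- runSeed
            ens <- trainEnsemble(subset, ecfg)
            decide <- function(feat) vote(ens, feat)$decision
          }
          dec <- vapply(tidx, function(i)
            decide(testPool$features[[i]]), integer(1))
          gen <- testPool$meta$subject_id[tidx] == s
          met <- confusionMetrics(sum(gen & dec == 1L), sum(gen & dec == 0L),
                                  sum(!gen & dec == 0L), sum(!gen & dec == 1L))
          rows[[length(rows) + 1L]] <- data.frame(
            fraction = f, method = method, run = r, subject = s,
            fold = d, n_train = 2L * nPer, accuracy = met$accuracy,
            FAR = met$far, FRR = met$frr, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Bagging-size sweep
#'
#' Runs the leave-one-day-out evaluation at each ensemble size and
#' collects subject-level accuracy/FAR/FRR (mean over folds).
#'
#' @param pool a [buildFeaturePool()].
#' @param sizes ensemble sizes M to evaluate.
#' @param cfg an [ensembleConfig()] (its `M` is overridden).
#' @param policy an [authPolicy()].
#' @param subjects restrict enrolled subjects.
#' @return data.frame: M, subject, accuracy, FAR, FRR (one row per M per
#'   subject).
#' @export
baggingSizeSweep <- function(pool, sizes = c(1L, 3L, 5L, 7L, 9L),
                             cfg = ensembleConfig(),
                             policy = authPolicy(), subjects = NULL) {
  stopifnot(all(sizes >= 1L))
  rows <- list()
  for (M in sizes) {
    ecfg <- cfg
    ecfg$M <- as.integer(M)
    rep <- leaveOneDayOut(pool, policy, ecfg, subjects = subjects)
    r <- rep$results
    for (s in unique(r$subject)) {
      rs <- r[r$subject == s, ]
      rows[[length(rows) + 1L]] <- data.frame(
        M = M, subject = s, accuracy = mean(rs$accuracy),
        FAR = mean(rs$FAR), FRR = mean(rs$FRR), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences `a - b`. Zero differences are
#' dropped (standard practice); at least 5 non-zero pairs are required.
#' The statistic is `min(V+, V-)`, the smaller of the positive- and
#' negative-rank sums. The null distribution is enumerated exactly over
#' all sign assignments for n <= 12 (ties handled through average
#' ranks); above that a tie-corrected normal approximation is used.
#'
#' @param a,b equal-length numeric vectors of paired values.
#' @param exactMax largest n for exact enumeration.
#' @return list with `statistic`, `p_value`, `n` (pairs used), `method`.
#' @export
wilcoxonSignedRank <- function(a, b, exactMax = 12L) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate test: all differences are zero", call. = FALSE)
  if (n < 5) stop(sprintf(
    "need >= 5 non-zero differences after dropping zeros, got %d", n),
    call. = FALSE)
  r <- rank(abs(d))
  vPlus <- sum(r[d > 0])
  vMinus <- sum(r[d < 0])
  stat <- min(vPlus, vMinus)
  if (n <= exactMax) {
    # exact: enumerate all 2^n sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vAll <- as.numeric(signs %*% r)
    pv <- 2 * min(mean(vAll <= vPlus), mean(vAll >= vPlus))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (vPlus - mu) / sqrt(sig2)
    pv <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(statistic = stat, p_value = min(pv, 1), n = n, method = method)
}
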
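#' Ensemble (bagging) configuration
#'
#' @param M ensemble (bagging) size: number of bootstrap-trained weak
#'   learners combined by majority vote.
#' @param base a [learnerConfig()] for the weak learners; each learner's
#'   seed is derived from `seed` and its index.
#' @param seed integer ensemble seed.
#' @param tieRule decision on an exact vote tie (even `M` only);
#'   `"reject"` fails closed.
#' @return validated `EnsembleConfig` (classed list).
#' @export
ensembleConfig <- function(M = 9L, base = learnerConfig(), seed = 1L,
                           tieRule = c("reject")) {
  tieRule <- match.arg(tieRule)
  cfg <- list(M = as.integer(M), base = base, seed = as.integer(seed),
              tieRule = tieRule)
  if (cfg$M < 1L)
    stop("invalid EnsembleConfig: field 'M' must be >= 1", call. = FALSE)
  class(cfg) <- c("EnsembleConfig", "list")
  cfg
}

#' Stratified bootstrap resample of a labeled set
#'
#' Draws, per class, a with-replacement sample of the same size as that
#' class, so the output has the same number of data points as the input
#' and both classes stay represented (a plain bootstrap of a small
#' balanced set can collapse to a single class, which is untrainable).
#'
#' @param data a [labeledSet()].
#' @param seed integer seed.
#' @return a [labeledSet()] of identical size.
#' @export
bootstrapSample <- function(data, seed) {
  stopifnot(inherits(data, "LabeledSet"))
  if (!length(data$labels)) stop("empty training set", call. = FALSE)
  set.seed(seed)
  idx <- sort(unlist(lapply(sort(unique(data$labels)), function(cl) {
    members <- which(data$labels == cl)
    members[sample.int(length(members), length(members), replace = TRUE)]
  }), use.names = FALSE))
  labeledSet(data$features[idx], data$labels[idx],
             meta = if (!is.null(data$meta)) data$meta[idx, , drop = FALSE])
}

#' Train a bagged authenticator
#'
#' Trains `M` weak learners, each on an independent seeded bootstrap
#' resample of `data`, and combines them by majority vote
#' (see [vote()]).
#'
#' @param data a [labeledSet()].
#' @param cfg an [ensembleConfig()].
#' @param context optional list `(subject_id, task, arm)` recorded on the
#'   model.
#' @return a [BaggedAuthenticator-class].
#' @export
trainEnsemble <- function(data, cfg = ensembleConfig(), context = list()) {
  learnersList <- lapply(seq_len(cfg$M), function(m) {
    boot <- bootstrapSample(data, mixSeed(cfg$seed, 21L, m))
    lcfg <- cfg$base
    lcfg$seed <- mixSeed(cfg$seed, 22L, m)
    trainLearner(boot, lcfg)
  })
  new("BaggedAuthenticator",
      learners = learnersList, config = unclass(cfg), context = context)
}

#' Majority-vote ensemble decision
#'
#' Each weak learner casts a Yes/No vote via [predictLearner()]; the
#' ensemble authenticates iff strictly more than `M/2` vote Yes. An exact
#' tie (even `M`) is rejected under the `"reject"` tie rule.
#'
#' @param ensemble a [BaggedAuthenticator-class].
#' @param features a [FeatureMatrix-class] or matrix.
#' @return list with `decision` (0/1), `yes_votes`, `votes` (per-learner
#'   decisions).
#' @export
vote <- function(ensemble, features) {
  stopifnot(is(ensemble, "BaggedAuthenticator"))
  votes <- vapply(ensemble@learners,
                  function(l) predictLearner(l, features)$decision,
                  integer(1))
  yes <- sum(votes)
  M <- length(votes)
  list(decision = as.integer(yes > M / 2), yes_votes = yes, votes = votes)
}

#' Serialize / restore a bagged authenticator
#'
#' Writes a directory with one learner container per weak learner plus a
#' JSON manifest (context, config, format version).
#'
#' @param ensemble a [BaggedAuthenticator-class].
#' @param dir directory to create/populate.
#' @return `readEnsemble()` returns the restored
#'   [BaggedAuthenticator-class].
#' @export
writeEnsemble <- function(ensemble, dir) {
  stopifnot(is(ensemble, "BaggedAuthenticator"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  M <- length(ensemble@learners)
  files <- sprintf("learner-%02d.json", seq_len(M))
  for (m in seq_len(M))
    writeLearner(ensemble@learners[[m]], file.path(dir, files[m]))
  cfg <- ensemble@config
  cfg$base <- unclass(cfg$base)
  manifest <- list(format = "neuroauth-ensemble-v1", M = M,
                   context = ensemble@context, config = cfg,
                   learner_files = files)
  jsonlite::write_json(manifest, file.path(dir, "ensemble.manifest"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeEnsemble
#' @export
readEnsemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "ensemble.manifest"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "neuroauth-ensemble-v1"))
    stop(sprintf("unrecognized ensemble container format in %s", dir),
         call. = FALSE)
  learnersList <- lapply(manifest$learner_files,
                         function(f) readLearner(file.path(dir, f)))
  ctx <- manifest$context
  new("BaggedAuthenticator",
      learners = learnersList,
      config = manifest$config,
      context = if (length(ctx)) as.list(ctx) else list())
}
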
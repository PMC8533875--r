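#' Weak-learner (shallow LSTM) configuration
#'
#' Architecture and optimization settings for the binary authenticator:
#' feature-frame sequence -> one LSTM layer -> fully connected layer ->
#' 2-unit softmax over {No, Yes}. Training minimizes cross-entropy with
#' the Adam optimizer; all weight initialization and batch shuffling is
#' driven by `seed`.
#'
#' @param hiddenUnits LSTM hidden state size.
#' @param epochs training passes over the data.
#' @param batchSize minibatch size.
#' @param learningRate Adam step size.
#' @param seed integer; same seed + data give identical parameters.
#' @param decisionThreshold authenticate when `p_yes >=` this value.
#' @param normalization `"zscore_train"` (per-feature-row z-score using
#'   training-set statistics) or `"none"`.
#' @return validated `LearnerConfig` (classed list).
#' @export
learnerConfig <- function(hiddenUnits = 64L, epochs = 60L, batchSize = 8L,
                          learningRate = 1e-3, seed = 1L,
                          decisionThreshold = 0.5,
                          normalization = c("zscore_train", "none")) {
  normalization <- match.arg(normalization)
  cfg <- list(hiddenUnits = as.integer(hiddenUnits),
              epochs = as.integer(epochs),
              batchSize = as.integer(batchSize),
              learningRate = learningRate, seed = as.integer(seed),
              decisionThreshold = decisionThreshold,
              normalization = normalization)
  if (any(c(cfg$hiddenUnits, cfg$epochs, cfg$batchSize) < 1L))
    stop("invalid LearnerConfig: counts must be positive", call. = FALSE)
  if (cfg$learningRate <= 0)
    stop("invalid LearnerConfig: field 'learningRate' must be positive", call. = FALSE)
  if (cfg$decisionThreshold <= 0 || cfg$decisionThreshold >= 1)
    stop("invalid LearnerConfig: field 'decisionThreshold' must lie in (0,1)",
         call. = FALSE)
  class(cfg) <- c("LearnerConfig", "list")
  cfg
}

#' Construct a labeled training set
#'
#' @param features list of [FeatureMatrix-class] (or plain matrices of
#'   identical shape).
#' @param labels integer vector, 0 = No/imposter, 1 = Yes/authorized.
#' @param meta optional data.frame of per-example provenance (subject,
#'   day, ...), carried along for audit.
#' @return `LabeledSet` (classed list).
#' @export
labeledSet <- function(features, labels, meta = NULL) {
  labels <- as.integer(labels)
  if (length(features) != length(labels))
    stop("features and labels must have equal length", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (imposter) or 1 (authorized)", call. = FALSE)
  out <- list(features = features, labels = labels, meta = meta)
  class(out) <- c("LabeledSet", "list")
  out
}

featAsMatrix <- function(f) {
  if (is(f, "FeatureMatrix")) f@P else as.matrix(f)
}

# stack a list of feature matrices into a D x T x n array
featCube <- function(features) {
  mats <- lapply(features, featAsMatrix)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("inconsistent feature matrix shapes in training data", call. = FALSE)
  array(unlist(mats, use.names = FALSE), dim = c(d[1], d[2], length(mats)))
}

#' Train an LSTM weak learner
#'
#' Consumes each feature matrix as a sequence of `n_frames` steps of
#' `n_rows`-dimensional inputs. With `normalization = "zscore_train"`,
#' per-feature-row mean/sd are computed on the training set only and
#' stored with the model. Training is deterministic given
#' `cfg$seed` and the data.
#'
#' @param data a [labeledSet()] containing at least one example of each
#'   class, all feature matrices of identical shape.
#' @param cfg a [learnerConfig()].
#' @return a [WeakLearner-class].
#' @export
trainLearner <- function(data, cfg = learnerConfig()) {
  stopifnot(inherits(data, "LabeledSet"))
  if (length(unique(data$labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  cube <- featCube(data$features)
  D <- dim(cube)[1]; Tn <- dim(cube)[2]; n <- dim(cube)[3]

  if (cfg$normalization == "zscore_train") {
    flat <- matrix(cube, nrow = D)  # D x (T*n)
    mu <- rowMeans(flat)
    sdv <- pmax(apply(flat, 1L, stats::sd), 1e-8)
  } else {
    mu <- numeric(D); sdv <- rep(1, D)
  }
  cube <- (cube - mu) / sdv  # recycles over dim 1

  H <- cfg$hiddenUnits
  set.seed(mixSeed(cfg$seed, 11L))
  r <- sqrt(6 / (D + H))
  w0 <- list(
    Wx = matrix(stats::runif(4 * H * D, -r, r), 4 * H, D),
    Wh = matrix(stats::runif(4 * H * H, -r, r), 4 * H, H),
    b = c(rep(0, H), rep(1, H), rep(0, 2 * H)),  # forget bias 1
    Wd = matrix(stats::runif(2 * H, -r, r), 2, H),
    bd = c(0, 0)
  )
  order <- t(vapply(seq_len(cfg$epochs),
                    function(e) sample.int(n) - 1L, integer(n)))
  fit <- lstm_train_cpp(cube, data$labels, w0, cfg$epochs,
                        cfg$batchSize, cfg$learningRate, order)
  fit$b <- as.numeric(fit$b); fit$bd <- as.numeric(fit$bd)
  new("WeakLearner",
      weights = fit,
      normStats = list(mean = mu, sd = sdv),
      config = unclass(cfg),
      inputDim = as.integer(D), nFrames = as.integer(Tn))
}

#' Predict with a weak learner
#'
#' Applies the stored normalization, runs the LSTM forward pass and the
#' softmax head. The decision is 1 (authenticate) iff
#' `p_yes >= decisionThreshold` (ties at the threshold accept).
#'
#' @param learner a [WeakLearner-class].
#' @param features a [FeatureMatrix-class] or matrix with `inputDim` rows.
#' @return list with `p_yes`, `p_no`, `decision`.
#' @export
predictLearner <- function(learner, features) {
  stopifnot(is(learner, "WeakLearner"))
  m <- featAsMatrix(features)
  if (nrow(m) != learner@inputDim)
    stop(sprintf("feature shape mismatch: learner expects %d rows, got %d",
                 learner@inputDim, nrow(m)), call. = FALSE)
  m <- (m - learner@normStats$mean) / learner@normStats$sd
  p <- lstm_prob_cpp(array(m, dim = c(dim(m), 1L)), learner@weights)
  pYes <- p[1, 2]
  list(p_yes = pYes, p_no = p[1, 1],
       decision = as.integer(pYes >= learner@config$decisionThreshold))
}

#' @describeIn predictLearner `predict` method for [WeakLearner-class].
#' @param object a [WeakLearner-class].
#' @param ... passed through (`features`).
#' @export
setMethod("predict", "WeakLearner", function(object, ...) {
  predictLearner(object, ...)
})

#' Serialize / restore a weak learner
#'
#' Writes parameters, normalization stats and config to a single JSON
#' container (text, versioned) loadable without retraining.
#'
#' @param learner a [WeakLearner-class].
#' @param path file path.
#' @return `readLearner()` returns the restored [WeakLearner-class].
#' @export
writeLearner <- function(learner, path) {
  stopifnot(is(learner, "WeakLearner"))
  obj <- list(
    format = "neuroauth-learner-v1",
    weights = lapply(learner@weights, function(w)
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(data = as.numeric(w))),
    normStats = learner@normStats,
    config = learner@config,
    inputDim = learner@inputDim, nFrames = learner@nFrames
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLearner
#' @export
readLearner <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "neuroauth-learner-v1"))
    stop(sprintf("unrecognized learner container format in %s", path),
         call. = FALSE)
  w <- lapply(obj$weights, function(x) {
    if (length(x$dim) == 2L) matrix(x$data, x$dim[1], x$dim[2])
    else as.numeric(x$data)
  })
  cfg <- obj$config
  cfg$normalization <- as.character(cfg$normalization)
  new("WeakLearner",
      weights = w,
      normStats = list(mean = as.numeric(obj$normStats$mean),
                       sd = as.numeric(obj$normStats$sd)),
      config = cfg,
      inputDim = as.integer(obj$inputDim),
      nFrames = as.integer(obj$nFrames))
}
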
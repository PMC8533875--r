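#' @useDynLib neuroauth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats fft predict
NULL

#' RawSession: one continuous multi-channel EEG recording
#'
#' Holds the continuous EEG of one subject on one recording day
#' (channels x time samples, microvolts) together with the trial event
#' markers. Events carry the sample index of task onset, the task
#' (`"performed"` or `"imagined"` movement) and the cued arm
#' (`"left"` or `"right"`).
#'
#' @slot subjectId character subject identifier.
#' @slot dayIndex integer recording day (1-based).
#' @slot samples numeric matrix, channels x time, in microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames character vector, one name per row of `samples`.
#' @slot epochS task epoch duration in seconds (window length implied by
#'   each event).
#' @slot events data.frame with columns `onset_sample` (1-based),
#'   `task`, `arm`, ordered by onset, non-overlapping task windows.
#'
#' @seealso [generateCohort()], [extractEpochs()], [writeSessionCsv()]
#' @export
setClass("RawSession",
  representation(
    subjectId = "character",
    dayIndex = "integer",
    samples = "matrix",
    samplingRate = "numeric",
    channelNames = "character",
    epochS = "numeric",
    events = "data.frame"
  )
)

setValidity("RawSession", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be length 1")
  if (length(object@dayIndex) != 1L || object@dayIndex < 1L)
    msg <- c(msg, "dayIndex must be a single positive integer")
  if (nrow(object@samples) != length(object@channelNames))
    msg <- c(msg, "channelNames length must equal number of sample rows")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  ev <- object@events
  need <- c("onset_sample", "task", "arm")
  if (!all(need %in% names(ev))) {
    msg <- c(msg, sprintf("events must have columns %s", paste(need, collapse = ", ")))
  } else if (nrow(ev) > 0L) {
    win <- round(object@epochS * object@samplingRate)
    if (any(ev$onset_sample < 1L))
      msg <- c(msg, "event onset_sample must be >= 1")
    if (any(ev$onset_sample + win - 1L > ncol(object@samples)))
      msg <- c(msg, "event window extends beyond end of recording")
    if (is.unsorted(ev$onset_sample, strictly = TRUE))
      msg <- c(msg, "events must be strictly ordered by onset")
    if (nrow(ev) > 1L && any(diff(ev$onset_sample) < win))
      msg <- c(msg, "event task windows must not overlap")
    if (!all(ev$task %in% c("performed", "imagined")))
      msg <- c(msg, "event task must be 'performed' or 'imagined'")
    if (!all(ev$arm %in% c("left", "right")))
      msg <- c(msg, "event arm must be 'left' or 'right'")
  }
  if (length(msg)) msg else TRUE
})

#' Epoch: one trial cut to the task window
#'
#' A single trial's EEG (channels x time samples) after preprocessing,
#' time-locked to the task-onset cue.
#'
#' @slot subjectId,dayIndex,task,arm trial provenance.
#' @slot samples numeric matrix, channels x time.
#' @slot samplingRate sampling rate (Hz) of `samples` (after resampling).
#' @slot channelNames channel labels, one per row.
#' @export
setClass("Epoch",
  representation(
    subjectId = "character",
    dayIndex = "integer",
    task = "character",
    arm = "character",
    samples = "matrix",
    samplingRate = "numeric",
    channelNames = "character"
  )
)

setValidity("Epoch", function(object) {
  if (nrow(object@samples) != length(object@channelNames))
    return("channelNames length must equal number of sample rows")
  if (!object@task %in% c("performed", "imagined")) return("bad task")
  if (!object@arm %in% c("left", "right")) return("bad arm")
  TRUE
})

#' Spectrogram: one-sided complex STFT of a single channel
#'
#' @slot values complex matrix, frequency bins x time frames.
#' @slot freqs bin center frequencies in Hz (one per row).
#' @slot frameTimes frame center times in seconds relative to epoch onset.
#' @export
setClass("Spectrogram",
  representation(
    values = "matrix",
    freqs = "numeric",
    frameTimes = "numeric"
  )
)

setValidity("Spectrogram", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@freqs))
    msg <- c(msg, "freqs length must equal number of rows")
  if (ncol(object@values) != length(object@frameTimes))
    msg <- c(msg, "frameTimes length must equal number of columns")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: sub-band dB power sequence for one epoch
#'
#' Rows are (channel, sub-band) pairs; columns are STFT frames. Values
#' are power in dB (20 log10 |X|). `mode` records the channel subset
#' used by [assembleFeatures()].
#'
#' @slot P numeric matrix, (channels x sub-bands) rows x frames.
#' @slot rowLabels "channel:band" label per row, in stacking order.
#' @slot mode `"paper_literal"` (5 central channels, 25 rows) or
#'   `"all_channels"` (all 8 channels, 40 rows with defaults).
#' @export
setClass("FeatureMatrix",
  representation(
    P = "matrix",
    rowLabels = "character",
    mode = "character"
  )
)

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  if (nrow(object@P) != length(object@rowLabels))
    msg <- c(msg, "rowLabels length must equal nrow(P)")
  if (!all(is.finite(object@P)))
    msg <- c(msg, "feature values must be finite (dB floor applied)")
  if (!object@mode %in% c("paper_literal", "all_channels"))
    msg <- c(msg, "mode must be 'paper_literal' or 'all_channels'")
  if (length(msg)) msg else TRUE
})

#' WeakLearner: a trained shallow LSTM binary authenticator
#'
#' Feature-frame sequence -> one LSTM layer -> fully connected layer ->
#' softmax over {No, Yes}. Gate weights are stored stacked in the order
#' input, forget, candidate, output.
#'
#' @slot weights list with `Wx` (4H x D), `Wh` (4H x H), `b` (4H),
#'   `Wd` (2 x H), `bd` (2).
#' @slot normStats per-feature-row mean and sd computed on the training
#'   set (z-score normalization), or NULL-equivalent when disabled.
#' @slot config the [learnerConfig()] used for training.
#' @slot inputDim number of feature rows expected at predict time.
#' @slot nFrames number of frames seen in training (informational).
#' @export
setClass("WeakLearner",
  representation(
    weights = "list",
    normStats = "list",
    config = "list",
    inputDim = "integer",
    nFrames = "integer"
  )
)

setValidity("WeakLearner", function(object) {
  w <- object@weights
  need <- c("Wx", "Wh", "b", "Wd", "bd")
  if (!all(need %in% names(w)))
    return(sprintf("weights must contain %s", paste(need, collapse = ", ")))
  H <- ncol(w$Wh)
  if (nrow(w$Wx) != 4L * H || nrow(w$Wh) != 4L * H || length(w$b) != 4L * H)
    return("gate weight shapes inconsistent with hidden size")
  if (ncol(w$Wx) != object@inputDim)
    return("Wx columns must equal inputDim")
  if (nrow(w$Wd) != 2L || ncol(w$Wd) != H || length(w$bd) != 2L)
    return("dense head must map H -> 2 classes")
  if (!all(vapply(object@normStats, function(x) all(is.finite(x)), logical(1))))
    return("normalization stats must be finite")
  TRUE
})

#' BaggedAuthenticator: majority-vote ensemble of LSTM weak learners
#'
#' @slot learners list of M [WeakLearner-class] objects, each trained on
#'   an independent bootstrap resample of the training set.
#' @slot config the [ensembleConfig()] used.
#' @slot context list with `subject_id`, `task`, `arm` (may be empty).
#' @export
setClass("BaggedAuthenticator",
  representation(
    learners = "list",
    config = "list",
    context = "list"
  )
)

setValidity("BaggedAuthenticator", function(object) {
  if (!length(object@learners)) return("ensemble must contain >= 1 learner")
  if (!all(vapply(object@learners, is, logical(1), "WeakLearner")))
    return("learners must all be WeakLearner objects")
  dims <- vapply(object@learners, function(l) l@inputDim, integer(1))
  if (length(unique(dims)) != 1L)
    return("all learners must share the feature input dimension")
  if (!is.null(object@config$M) && length(object@learners) != object@config$M)
    return("number of learners must equal config M")
  TRUE
})

#' SubjectModel: enrollment of one subject under an authentication policy
#'
#' One [BaggedAuthenticator-class] per task in the policy, plus the
#' imposter pool the negatives were drawn from and the scenario
#' (`known_imposters`: all other subjects seen during training;
#' `unseen_imposters`: a held-out group never used for training).
#'
#' @slot subjectId enrolled subject.
#' @slot authenticators named list, one ensemble per policy task key.
#' @slot scenario `"known_imposters"` or `"unseen_imposters"`.
#' @slot imposterPool subject ids whose epochs served as negatives.
#' @slot policy the [authPolicy()] used.
#' @export
setClass("SubjectModel",
  representation(
    subjectId = "character",
    authenticators = "list",
    scenario = "character",
    imposterPool = "character",
    policy = "list"
  )
)

setValidity("SubjectModel", function(object) {
  if (!object@scenario %in% c("known_imposters", "unseen_imposters"))
    return("scenario must be 'known_imposters' or 'unseen_imposters'")
  if (object@subjectId %in% object@imposterPool)
    return("enrolled subject must not be in its own imposter pool")
  keys <- vapply(object@policy$tasks, function(t) taskKey(t$task, t$arm), character(1))
  if (!setequal(names(object@authenticators), keys))
    return("authenticators must cover exactly the policy tasks")
  TRUE
})
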
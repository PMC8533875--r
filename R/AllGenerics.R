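#' Accessors for neuroauth objects
#'
#' Small accessor family: `subjectId()`, `dayIndex()`, `eegSamples()`,
#' `samplingRate()`, `channelNames()`, `events()`, `featureValues()`,
#' `rowLabels()`, `learners()`.
#'
#' @param object a neuroauth S4 object.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("dayIndex", function(object) standardGeneric("dayIndex"))
#' @rdname accessors
#' @export
setGeneric("eegSamples", function(object) standardGeneric("eegSamples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("rowLabels", function(object) standardGeneric("rowLabels"))
#' @rdname accessors
#' @export
setGeneric("learners", function(object) standardGeneric("learners"))

#' @rdname accessors
setMethod("subjectId", "RawSession", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "Epoch", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "SubjectModel", function(object) object@subjectId)
#' @rdname accessors
setMethod("dayIndex", "RawSession", function(object) object@dayIndex)
#' @rdname accessors
setMethod("dayIndex", "Epoch", function(object) object@dayIndex)
#' @rdname accessors
setMethod("eegSamples", "RawSession", function(object) object@samples)
#' @rdname accessors
setMethod("eegSamples", "Epoch", function(object) object@samples)
#' @rdname accessors
setMethod("samplingRate", "RawSession", function(object) object@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "Epoch", function(object) object@samplingRate)
#' @rdname accessors
setMethod("channelNames", "RawSession", function(object) object@channelNames)
#' @rdname accessors
setMethod("channelNames", "Epoch", function(object) object@channelNames)
#' @rdname accessors
setMethod("events", "RawSession", function(object) object@events)
#' @rdname accessors
setMethod("featureValues", "FeatureMatrix", function(object) object@P)
#' @rdname accessors
setMethod("rowLabels", "FeatureMatrix", function(object) object@rowLabels)
#' @rdname accessors
setMethod("learners", "BaggedAuthenticator", function(object) object@learners)

setMethod("show", "RawSession", function(object) {
  cat(sprintf(
    "RawSession: subject %s, day %d\n  %d channels x %d samples @ %g Hz (%.1f s)\n  %d events (%d performed, %d imagined)\n",
    object@subjectId, object@dayIndex,
    nrow(object@samples), ncol(object@samples), object@samplingRate,
    ncol(object@samples) / object@samplingRate,
    nrow(object@events),
    sum(object@events$task == "performed"),
    sum(object@events$task == "imagined")
  ))
})

setMethod("show", "Epoch", function(object) {
  cat(sprintf(
    "Epoch: subject %s, day %d, %s/%s, %d x %d @ %g Hz\n",
    object@subjectId, object@dayIndex, object@task, object@arm,
    nrow(object@samples), ncol(object@samples), object@samplingRate
  ))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf(
    "Spectrogram: %d bins x %d frames, %g-%g Hz (res %.5g Hz)\n",
    nrow(object@values), ncol(object@values),
    min(object@freqs), max(object@freqs),
    if (length(object@freqs) > 1) diff(object@freqs[1:2]) else NA_real_
  ))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf(
    "FeatureMatrix (%s): %d rows x %d frames, range [%.1f, %.1f] dB\n",
    object@mode, nrow(object@P), ncol(object@P),
    min(object@P), max(object@P)
  ))
})

setMethod("show", "WeakLearner", function(object) {
  H <- ncol(object@weights$Wh)
  cat(sprintf(
    "WeakLearner: LSTM(%d inputs -> %d hidden) -> dense(2) -> softmax\n",
    object@inputDim, H
  ))
})

setMethod("show", "BaggedAuthenticator", function(object) {
  ctx <- object@context
  ctxs <- if (length(ctx)) {
    sprintf(" [%s %s/%s]", ctx$subject_id, ctx$task, ctx$arm)
  } else ""
  cat(sprintf(
    "BaggedAuthenticator%s: M = %d weak learners, majority vote\n",
    ctxs, length(object@learners)
  ))
})

setMethod("show", "SubjectModel", function(object) {
  cat(sprintf(
    "SubjectModel: subject %s (%s)\n  tasks: %s\n  imposter pool: %d subjects\n",
    object@subjectId, object@scenario,
    paste(names(object@authenticators), collapse = ", "),
    length(object@imposterPool)
  ))
})
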
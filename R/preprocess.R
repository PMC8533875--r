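#' Preprocessing configuration
#'
#' @param filterOrder Butterworth prototype order (even, positive);
#'   the band-pass is applied forward-backward (zero phase), so the
#'   effective magnitude response is the squared order-`filterOrder`
#'   band-pass response.
#' @param band numeric length 2, band-pass edges in Hz.
#' @param targetRate rate after downsampling, Hz.
#' @param epochS epoch length, seconds.
#' @return validated `PreprocessConfig` (classed list).
#' @export
preprocessConfig <- function(filterOrder = 4L, band = c(1, 30),
                             targetRate = 100, epochS = 3) {
  cfg <- list(filterOrder = as.integer(filterOrder),
              band = as.numeric(band),
              targetRate = targetRate, epochS = epochS)
  if (cfg$filterOrder <= 0L || cfg$filterOrder %% 2L != 0L)
    stop("invalid PreprocessConfig: field 'filterOrder' must be a positive even count",
         call. = FALSE)
  if (length(cfg$band) != 2L || cfg$band[1] <= 0 ||
      cfg$band[1] >= cfg$band[2] || cfg$band[2] >= cfg$targetRate / 2)
    stop("invalid PreprocessConfig: field 'band' must satisfy 0 < low < high < targetRate/2",
         call. = FALSE)
  class(cfg) <- c("PreprocessConfig", "list")
  cfg
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`filterOrder` Butterworth band-pass per channel,
#' forward and backward ([signal::filtfilt()]) so the phase response is
#' zero and the task windows are not delayed. Passband gain is ~1,
#' stopband attenuation is the squared single-pass magnitude.
#'
#' @param samples channels x time numeric matrix (a single channel may be
#'   passed as a vector).
#' @param rate sampling rate of `samples`, Hz.
#' @param cfg a [preprocessConfig()].
#' @return filtered matrix (or vector), same shape.
#' @export
bandpassFilter <- function(samples, rate, cfg = preprocessConfig()) {
  if (rate <= 2 * cfg$band[2])
    stop(sprintf(
      "configuration error: band high edge %g Hz requires rate > %g Hz, got %g",
      cfg$band[2], 2 * cfg$band[2], rate), call. = FALSE)
  bf <- signal::butter(cfg$filterOrder, cfg$band / (rate / 2), type = "pass")
  vec <- is.null(dim(samples))
  m <- if (vec) matrix(samples, nrow = 1) else samples
  out <- t(apply(m, 1L, function(x) signal::filtfilt(bf, x)))
  if (vec) drop(out) else out
}

#' Resample channels to the target rate
#'
#' Rational-rate polyphase resampling ([signal::resample()]) from `rate`
#' to `cfg$targetRate` (250 -> 100 Hz is a 2/5 change). The input is
#' assumed band-limited below `targetRate/2`, which holds after
#' [bandpassFilter()]. Output length is `round(n * targetRate / rate)`.
#'
#' @inheritParams bandpassFilter
#' @return resampled matrix (or vector) at `cfg$targetRate`.
#' @export
resampleToTarget <- function(samples, rate, cfg = preprocessConfig()) {
  vec <- is.null(dim(samples))
  m <- if (vec) matrix(samples, nrow = 1) else samples
  if (ncol(m) == 0L) stop("zero-length input to resampleToTarget", call. = FALSE)
  if (isTRUE(all.equal(rate, cfg$targetRate))) {
    return(if (vec) drop(m) else m)
  }
  frac <- ratApprox(cfg$targetRate / rate)
  nOut <- as.integer(round(ncol(m) * cfg$targetRate / rate))
  out <- t(apply(m, 1L, function(x) {
    y <- signal::resample(x, frac[1], frac[2])
    length(y) <- nOut  # resample may over/under-shoot by a sample
    y[is.na(y)] <- 0
    y
  }))
  if (vec) drop(out) else out
}

# small-denominator rational approximation p/q of a positive ratio
ratApprox <- function(r, maxDen = 1000L) {
  for (q in seq_len(maxDen)) {
    p <- round(r * q)
    if (p >= 1 && abs(p / q - r) < 1e-9) return(c(p, q))
  }
  stop(sprintf("cannot express rate ratio %g as a small rational", r),
       call. = FALSE)
}

#' Preprocess a session and cut task epochs
#'
#' Pipeline order: band-pass filter the whole continuous recording (no
#' per-epoch edge transients), resample to the target rate, then cut one
#' [Epoch-class] per event at the task window. With defaults each epoch
#' is channels x 300 samples (3 s at 100 Hz).
#'
#' @param session a [RawSession-class].
#' @param cfg a [preprocessConfig()].
#' @return list of [Epoch-class], in event order.
#' @export
extractEpochs <- function(session, cfg = preprocessConfig()) {
  stopifnot(is(session, "RawSession"))
  validObject(session)
  ev <- session@events
  if (nrow(ev) == 0L) return(list())
  filtered <- bandpassFilter(session@samples, session@samplingRate, cfg)
  res <- resampleToTarget(filtered, session@samplingRate, cfg)
  if (is.null(dim(res))) res <- matrix(res, nrow = 1)
  ratio <- cfg$targetRate / session@samplingRate
  nT <- as.integer(round(cfg$epochS * cfg$targetRate))
  lapply(seq_len(nrow(ev)), function(e) {
    start <- as.integer(floor((ev$onset_sample[e] - 1L) * ratio)) + 1L
    stopSmp <- start + nT - 1L
    if (stopSmp > ncol(res))
      stop(sprintf(
        "event %d (onset %d): epoch window exceeds recording after resampling",
        e, ev$onset_sample[e]), call. = FALSE)
    new("Epoch",
        subjectId = session@subjectId, dayIndex = session@dayIndex,
        task = ev$task[e], arm = ev$arm[e],
        samples = res[, start:stopSmp, drop = FALSE],
        samplingRate = cfg$targetRate,
        channelNames = session@channelNames)
  })
}
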
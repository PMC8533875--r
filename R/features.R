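#' STFT configuration
#'
#' The nominal dialect is 128-point segments with 98% overlap of a
#' 300-sample (3 s at 100 Hz) epoch. A 98% overlap of 128 samples implies
#' a non-integer hop of 2.56 samples; the realizable dialect used here
#' fixes `hop = 3` (overlap 125 samples, ~97.7%) and symmetrically
#' zero-pads each 300-sample epoch to `padTo = 330`, which makes the
#' frame count exactly `floor((330 - 128)/3) + 1 = 68`, i.e. a 65 x 68
#' one-sided spectrogram at 100 Hz.
#'
#' @param nFft segment/FFT length (points).
#' @param window taper name; only `"hanning"` is provided.
#' @param overlapFraction nominal overlap fraction (documentation of the
#'   dialect; the realized hop is `hop`).
#' @param padTo symmetric zero-pad target length, samples; `NA` disables
#'   padding.
#' @param hop frame advance, samples.
#' @return validated `StftConfig` (classed list).
#' @export
stftConfig <- function(nFft = 128L, window = "hanning",
                       overlapFraction = 0.98, padTo = 330L, hop = 3L) {
  cfg <- list(nFft = as.integer(nFft), window = window,
              overlapFraction = overlapFraction,
              padTo = if (is.na(padTo)) NA_integer_ else as.integer(padTo),
              hop = as.integer(hop))
  if (cfg$hop < 1L) stop("invalid StftConfig: field 'hop' must be >= 1", call. = FALSE)
  if (cfg$nFft < cfg$hop)
    stop("invalid StftConfig: field 'nFft' must be >= hop", call. = FALSE)
  if (overlapFraction < 0 || overlapFraction >= 1)
    stop("invalid StftConfig: field 'overlapFraction' must lie in [0, 1)", call. = FALSE)
  if (!identical(window, "hanning"))
    stop("invalid StftConfig: field 'window' must be 'hanning'", call. = FALSE)
  class(cfg) <- c("StftConfig", "list")
  cfg
}

#' Short-time Fourier transform of one channel
#'
#' Symmetrically zero-pads the input to `padTo`, slides a Hanning-tapered
#' `nFft`-point segment with advance `hop`, and returns the one-sided
#' complex spectrum per frame (`nFft/2 + 1` rows). With defaults a
#' 300-sample epoch yields 65 rows x 68 frames with 100/128 = 0.78125 Hz
#' bin spacing.
#'
#' @param x numeric vector, one channel of one epoch.
#' @param cfg a [stftConfig()].
#' @param rate sampling rate of `x`, Hz (sets the frequency axis).
#' @return a [Spectrogram-class].
#' @export
stft <- function(x, cfg = stftConfig(), rate = 100) {
  n <- length(x)
  padTo <- if (is.na(cfg$padTo)) n else max(cfg$padTo, n)
  padL <- (padTo - n) %/% 2L
  xp <- c(numeric(padL), x, numeric(padTo - n - padL))
  if (length(xp) < cfg$nFft)
    stop(sprintf("input of length %d (padded %d) shorter than nFft = %d",
                 n, length(xp), cfg$nFft), call. = FALSE)
  starts <- seq.int(1L, length(xp) - cfg$nFft + 1L, by = cfg$hop)
  w <- signal::hanning(cfg$nFft)
  frames <- vapply(starts,
                   function(s) xp[s:(s + cfg$nFft - 1L)] * w,
                   numeric(cfg$nFft))
  spec <- stats::mvfft(frames)
  nFreq <- cfg$nFft %/% 2L + 1L
  new("Spectrogram",
      values = spec[seq_len(nFreq), , drop = FALSE],
      freqs = (seq_len(nFreq) - 1) * rate / cfg$nFft,
      frameTimes = (starts - 1L + cfg$nFft / 2 - padL) / rate)
}

#' Power in dB of a complex spectrum
#'
#' `20 * log10(|X|)`, with magnitudes floored at `eps` so silent bins map
#' to a finite dB floor instead of -Inf.
#'
#' @param X complex (or numeric) matrix or [Spectrogram-class].
#' @param eps magnitude floor.
#' @return real matrix of dB power, same shape.
#' @export
powerDb <- function(X, eps = 1e-12) {
  if (is(X, "Spectrogram")) X <- X@values
  20 * log10(pmax(Mod(X), eps))
}

#' Sub-band grouping scheme
#'
#' Defaults split the mu (7-11 Hz) and beta (11-30 Hz) range into the
#' five sub-bands 7-11, 11-16, 16-21, 21-25 and 25-30 Hz. Bin membership
#' is half-open `[low, high)` on bin center frequencies so shared edges
#' are never double counted.
#'
#' @param bands list of `c(low, high)` pairs, ordered, non-overlapping
#'   interiors.
#' @return validated `SubbandScheme` (classed list).
#' @export
subbandScheme <- function(bands = synthBands()) {
  bands <- lapply(bands, as.numeric)
  lows <- vapply(bands, `[`, numeric(1), 1L)
  highs <- vapply(bands, `[`, numeric(1), 2L)
  if (any(lows >= highs))
    stop("invalid SubbandScheme: field 'bands' must have low < high", call. = FALSE)
  if (any(lows <= 0))
    stop("invalid SubbandScheme: field 'bands' must be positive", call. = FALSE)
  if (length(bands) > 1L && any(lows[-1] < highs[-length(bands)]))
    stop("invalid SubbandScheme: field 'bands' must be ordered and non-overlapping",
         call. = FALSE)
  scheme <- list(bands = bands, binRule = "half_open")
  class(scheme) <- c("SubbandScheme", "list")
  scheme
}

#' Collapse a spectrogram to sub-band mean dB power
#'
#' Row *b* of the result is the arithmetic mean, over frequency bins
#' whose center lies in `[low_b, high_b)`, of the dB power (Eq.
#' `20 log10 |X|`) in each frame. With defaults: 5 x 68.
#'
#' @param spgram a [Spectrogram-class].
#' @param scheme a [subbandScheme()].
#' @param eps magnitude floor passed to [powerDb()].
#' @return numeric matrix, bands x frames.
#' @export
subbandMatrix <- function(spgram, scheme = subbandScheme(), eps = 1e-12) {
  stopifnot(is(spgram, "Spectrogram"))
  P <- powerDb(spgram@values, eps)
  out <- matrix(NA_real_, nrow = length(scheme$bands), ncol = ncol(P))
  for (b in seq_along(scheme$bands)) {
    lo <- scheme$bands[[b]][1]; hi <- scheme$bands[[b]][2]
    members <- which(spgram@freqs >= lo & spgram@freqs < hi)
    if (!length(members))
      stop(sprintf(
        "configuration error: sub-band [%g, %g) Hz contains no frequency bins",
        lo, hi), call. = FALSE)
    out[b, ] <- colMeans(P[members, , drop = FALSE])
  }
  out
}

#' Assemble the per-trial feature matrix
#'
#' Computes the sub-band dB power matrix per channel and stacks them
#' row-wise. `mode = "all_channels"` (default) uses every channel of the
#' epoch (8 x 5 = 40 rows with defaults); `mode = "paper_literal"` uses
#' the five central/midline motor-relevant channels Fz, C3, Cz, C4, Pz
#' (25 rows), the smallest channel set consistent with a 25-row stacking
#' of 5-row per-channel matrices.
#'
#' @param epoch an [Epoch-class].
#' @param cfg a [stftConfig()].
#' @param scheme a [subbandScheme()].
#' @param mode `"all_channels"` or `"paper_literal"`.
#' @return a [FeatureMatrix-class] with `rowLabels` `"channel:lo-hi"` in
#'   stacking order.
#' @export
assembleFeatures <- function(epoch, cfg = stftConfig(),
                             scheme = subbandScheme(),
                             mode = c("all_channels", "paper_literal")) {
  stopifnot(is(epoch, "Epoch"))
  mode <- match.arg(mode)
  chans <- if (mode == "paper_literal") {
    need <- c("Fz", "C3", "Cz", "C4", "Pz")
    missing <- setdiff(need, epoch@channelNames)
    if (length(missing))
      stop(sprintf("paper_literal mode requires channels %s; missing: %s",
                   paste(need, collapse = ", "),
                   paste(missing, collapse = ", ")), call. = FALSE)
    need
  } else {
    epoch@channelNames
  }
  bandLab <- vapply(scheme$bands,
                    function(b) sprintf("%g-%g", b[1], b[2]), character(1))
  blocks <- lapply(chans, function(ch) {
    i <- match(ch, epoch@channelNames)
    subbandMatrix(stft(epoch@samples[i, ], cfg, epoch@samplingRate), scheme)
  })
  new("FeatureMatrix",
      P = do.call(rbind, blocks),
      rowLabels = as.vector(vapply(chans, function(ch)
        paste0(ch, ":", bandLab), character(length(bandLab)))),
      mode = mode)
}
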
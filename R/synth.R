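#' Derive a reproducible sub-seed from a global seed
#'
#' Splitmix-style integer mixing used to give every subject, day and
#' processing stage its own independent, reproducible random stream from
#' one global seed. Constants are arbitrary odd multipliers; state stays
#' below 2^31 so arithmetic is exact in doubles.
#'
#' @param seed global integer seed.
#' @param ... further integer stream indices (stage, subject, day, ...).
#' @return a single integer usable with [set.seed()].
#' @export
mixSeed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (k in as.numeric(c(...))) {
    s <- (s * 1103515 + (k %% 65536) * 2654435 + 12345) %% 2147483647
  }
  as.integer(s)
}

#' Specification of a synthetic chronic EEG cohort
#'
#' Bundles the study-design parameters (subjects, days, trials, trial
#' timing, montage) and the generator parameters that give each subject a
#' discriminable spectral identity. Defaults emulate a chronic
#' authentication study: 15 subjects, 5 recording days, 10 performed plus
#' 10 imagined motor trials per day (5 left / 5 right arm each), 3-s task
#' epochs, 8 dry electrodes at 250 Hz.
#'
#' Generator parameters: each subject draws per-channel, per-sub-band
#' oscillatory power gains (log-normal, `bandGainDispersion` = sdlog), a
#' 1/f background, and an event-related desynchronization (ERD) depth
#' applied to the central channel contralateral to the cued arm (C3 for
#' right, C4 for left) during the task window. Imagined-movement ERD is
#' `imaginedErdFactor` times the performed depth. Each day applies a
#' multiplicative per-channel gain jitter, a small channel-leakage mixing
#' matrix (electrode re-placement surrogate) and a noise-scale factor.
#'
#' @param nSubjects,nDays,trialsPerTask cohort design counts;
#'   `trialsPerTask` must be even (equal left/right split) and applies to
#'   each of the performed and imagined tasks.
#' @param samplingRate acquisition rate, Hz.
#' @param nChannels,channelNames montage.
#' @param epochS task epoch length, seconds.
#' @param seed global integer seed; the whole cohort is a pure function
#'   of the spec including this seed.
#' @param bandGainDispersion sdlog of the log-normal per-(channel, band)
#'   gains: the subject-separability dial.
#' @param erdDepth performed-task ERD depth, fraction of band power
#'   suppressed in `[0, 1)`.
#' @param imaginedErdFactor imagined ERD depth = factor x `erdDepth`.
#' @param backgroundExponent 1/f^exponent slope of the background.
#' @param backgroundSd background noise scale, microvolts.
#' @param oscSd base oscillation amplitude per sub-band, microvolts.
#' @param dayGainSd,dayLeakage,dayNoiseSd day-to-day variability: sdlog of
#'   per-channel gain jitter, off-diagonal mass of the leakage matrix,
#'   sdlog of the noise-scale factor.
#' @param sensorNoiseSd additive white sensor noise, microvolts.
#' @param maxFreq generator band limit, Hz (content above is zero, so a
#'   downstream resample to >= 2 x `maxFreq` is alias-safe).
#' @param cueS,restS seconds of cue before and rest after each task.
#' @return a validated `CohortSpec` (classed list).
#' @seealso [generateCohort()]
#' @export
cohortSpec <- function(nSubjects = 15L, nDays = 5L, trialsPerTask = 10L,
                       samplingRate = 250, nChannels = 8L,
                       channelNames = c("Fz", "C3", "Cz", "C4",
                                        "Pz", "PO7", "Oz", "PO8"),
                       epochS = 3, seed = 1L,
                       bandGainDispersion = 0.4,
                       erdDepth = 0.5, imaginedErdFactor = 0.7,
                       backgroundExponent = 1.0,
                       backgroundSd = 2, oscSd = 3,
                       dayGainSd = 0.08, dayLeakage = 0.05,
                       dayNoiseSd = 0.08, sensorNoiseSd = 0.5,
                       maxFreq = 45, cueS = 2, restS = 4) {
  spec <- list(
    nSubjects = as.integer(nSubjects), nDays = as.integer(nDays),
    trialsPerTask = as.integer(trialsPerTask),
    samplingRate = samplingRate, nChannels = as.integer(nChannels),
    channelNames = channelNames, epochS = epochS, seed = as.integer(seed),
    bandGainDispersion = bandGainDispersion, erdDepth = erdDepth,
    imaginedErdFactor = imaginedErdFactor,
    backgroundExponent = backgroundExponent,
    backgroundSd = backgroundSd, oscSd = oscSd,
    dayGainSd = dayGainSd, dayLeakage = dayLeakage,
    dayNoiseSd = dayNoiseSd, sensorNoiseSd = sensorNoiseSd,
    maxFreq = maxFreq, cueS = cueS, restS = restS
  )
  class(spec) <- c("CohortSpec", "list")
  validateCohortSpec(spec)
  spec
}

validateCohortSpec <- function(spec) {
  chk <- function(cond, field, what) {
    if (!cond) stop(sprintf("invalid CohortSpec: field '%s' %s", field, what),
                    call. = FALSE)
  }
  for (f in c("nSubjects", "nDays", "trialsPerTask", "nChannels"))
    chk(length(spec[[f]]) == 1L && spec[[f]] >= 1L, f, "must be a positive count")
  chk(spec$trialsPerTask %% 2L == 0L, "trialsPerTask",
      "must be even (equal left/right split)")
  chk(spec$samplingRate > 0, "samplingRate", "must be positive")
  chk(spec$samplingRate >= 2 * spec$maxFreq, "samplingRate",
      "must be >= 2 x maxFreq (Nyquist)")
  chk(length(spec$channelNames) == spec$nChannels, "channelNames",
      "must have one label per channel")
  chk(spec$epochS > 0, "epochS", "must be positive")
  chk(spec$erdDepth >= 0 && spec$erdDepth < 1, "erdDepth",
      "must lie in [0, 1)")
  chk(spec$imaginedErdFactor >= 0 && spec$imaginedErdFactor <= 1,
      "imaginedErdFactor", "must lie in [0, 1]")
  chk(spec$dayLeakage >= 0 && spec$dayLeakage < 0.5, "dayLeakage",
      "must lie in [0, 0.5)")
  chk(spec$bandGainDispersion >= 0, "bandGainDispersion",
      "must be non-negative")
  invisible(TRUE)
}

# canonical sub-band edges, Hz (mu 7-11, beta split 11-30)
synthBands <- function() {
  list(c(7, 11), c(11, 16), c(16, 21), c(21, 25), c(25, 30))
}

#' Draw a subject's spectral fingerprint
#'
#' Per-(channel, sub-band) oscillatory power gains plus ERD depths per
#' (task, arm) and a background 1/f exponent, drawn reproducibly from the
#' cohort seed.
#'
#' @param spec a [cohortSpec()].
#' @param subjectIndex subject number, 1-based.
#' @return list with `subject_id`, `band_gains` (channels x 5, strictly
#'   positive), `erd_depth` (2 x 2 matrix task x arm), `background_exponent`.
#' @export
subjectFingerprint <- function(spec, subjectIndex) {
  set.seed(mixSeed(spec$seed, 1L, subjectIndex))
  nb <- length(synthBands())
  gains <- matrix(
    exp(stats::rnorm(spec$nChannels * nb, 0, spec$bandGainDispersion)),
    nrow = spec$nChannels, ncol = nb,
    dimnames = list(spec$channelNames, NULL)
  )
  erd <- matrix(
    c(spec$erdDepth, spec$erdDepth,
      spec$erdDepth * spec$imaginedErdFactor,
      spec$erdDepth * spec$imaginedErdFactor),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("performed", "imagined"), c("left", "right"))
  )
  list(
    subject_id = sprintf("S%02d", subjectIndex),
    band_gains = gains,
    erd_depth = erd,
    background_exponent = spec$backgroundExponent
  )
}

#' Draw one day's recording-condition effect
#'
#' Multiplicative per-channel gain jitter, a row-stochastic channel
#' leakage matrix (off-diagonal mass = `dayLeakage`) standing in for
#' slightly different electrode placement, and a noise-scale factor.
#'
#' @param spec a [cohortSpec()].
#' @param subjectIndex,dayIndex indices, 1-based.
#' @return list with `gain_jitter`, `mixing`, `noise_scale`.
#' @export
dayEffect <- function(spec, subjectIndex, dayIndex) {
  set.seed(mixSeed(spec$seed, 2L, subjectIndex, dayIndex))
  nc <- spec$nChannels
  gain <- exp(stats::rnorm(nc, 0, spec$dayGainSd))
  mixing <- diag(1 - spec$dayLeakage, nc)
  if (nc > 1L && spec$dayLeakage > 0) {
    for (i in seq_len(nc)) {
      w <- stats::runif(nc - 1L)
      mixing[i, -i] <- spec$dayLeakage * w / sum(w)
    }
  } else {
    mixing <- diag(1, nc)
  }
  list(
    gain_jitter = gain,
    mixing = mixing,
    noise_scale = exp(stats::rnorm(1, 0, spec$dayNoiseSd))
  )
}

# white Gaussian noise shaped to 1/f^exponent, band-limited to (0, maxFreq],
# unit variance
coloredNoise <- function(n, fs, exponent, maxFreq) {
  white <- stats::rnorm(n)
  fr <- fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  amp <- ifelse(f > 0 & f <= maxFreq, 1 / pmax(f, 0.5)^(exponent / 2), 0)
  x <- Re(fft(fr * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# unit-variance narrow-band Gaussian noise with support [lo, hi) Hz
bandNoise <- function(n, fs, lo, hi) {
  white <- stats::rnorm(n)
  fr <- fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  amp <- as.numeric(f >= lo & f < hi)
  x <- Re(fft(fr * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# per-session trial schedule: performed block then imagined block,
# trialsPerTask trials each, arms balanced and shuffled within block
sessionEvents <- function(spec, rngSeed) {
  set.seed(rngSeed)
  fs <- spec$samplingRate
  trialLen <- spec$cueS + spec$epochS + spec$restS
  leadIn <- 2
  onsets <- integer(0); tasks <- character(0); arms <- character(0)
  k <- 0L
  for (task in c("performed", "imagined")) {
    armSeq <- sample(rep(c("left", "right"), spec$trialsPerTask / 2L))
    for (a in armSeq) {
      t0 <- leadIn + k * trialLen + spec$cueS
      onsets <- c(onsets, as.integer(round(t0 * fs)) + 1L)
      tasks <- c(tasks, task)
      arms <- c(arms, a)
      k <- k + 1L
    }
  }
  total <- as.integer(round((leadIn + k * trialLen + 1) * fs))
  list(
    events = data.frame(onset_sample = onsets, task = tasks, arm = arms,
                        stringsAsFactors = FALSE),
    totalSamples = total
  )
}

# build one subject-day session: background + per-band oscillations with
# ERD on the contralateral central channel, then the day transform
synthSession <- function(spec, fp, de, subjectIndex, dayIndex) {
  sched <- sessionEvents(spec, mixSeed(spec$seed, 4L, subjectIndex, dayIndex))
  set.seed(mixSeed(spec$seed, 3L, subjectIndex, dayIndex))
  n <- sched$totalSamples
  fs <- spec$samplingRate
  nc <- spec$nChannels
  bands <- synthBands()
  win <- as.integer(round(spec$epochS * fs))
  ev <- sched$events

  contra <- c(left = match("C4", spec$channelNames),
              right = match("C3", spec$channelNames))

  x <- matrix(0, nrow = nc, ncol = n)
  for (ch in seq_len(nc)) {
    bg <- coloredNoise(n, fs, fp$background_exponent, spec$maxFreq) *
      spec$backgroundSd * de$noise_scale
    sens <- bandNoise(n, fs, 0.5, spec$maxFreq) *
      spec$sensorNoiseSd * de$noise_scale
    tot <- bg + sens
    for (b in seq_along(bands)) {
      osc <- bandNoise(n, fs, bands[[b]][1], bands[[b]][2]) *
        spec$oscSd * fp$band_gains[ch, b]
      # ERD: suppress band power on the contralateral central channel
      # during each task window; 50 ms cosine ramps keep the envelope
      # band-limited (no spectral splatter above the generator band)
      for (e in seq_len(nrow(ev))) {
        tgt <- contra[[ev$arm[e]]]
        if (!is.na(tgt) && tgt == ch) {
          depth <- fp$erd_depth[ev$task[e], ev$arm[e]]
          s <- sqrt(1 - depth)
          idx <- ev$onset_sample[e]:(ev$onset_sample[e] + win - 1L)
          env <- rep(s, win)
          nr <- min(as.integer(round(0.05 * fs)), win %/% 2L)
          if (nr > 0L) {
            ramp <- (1 + cos(seq(0, pi, length.out = nr))) / 2  # 1 -> 0
            env[seq_len(nr)] <- s + (1 - s) * ramp
            env[win - nr + seq_len(nr)] <- s + (1 - s) * rev(ramp)
          }
          osc[idx] <- osc[idx] * env
        }
      }
      tot <- tot + osc
    }
    x[ch, ] <- tot
  }
  x <- de$mixing %*% (de$gain_jitter * x)

  new("RawSession",
      subjectId = fp$subject_id, dayIndex = as.integer(dayIndex),
      samples = x, samplingRate = fs, channelNames = spec$channelNames,
      epochS = spec$epochS, events = ev)
}

#' Generate a synthetic chronic EEG cohort
#'
#' Produces `nSubjects x nDays` [RawSession-class] objects. Each session
#' contains `trialsPerTask` performed and `trialsPerTask` imagined motor
#' trials (half left, half right arm, shuffled within task block). Task
#' epochs express the subject's spectral fingerprint (per-channel,
#' per-sub-band power gains) with ERD-style band-power suppression on the
#' central channel contralateral to the cued arm, on top of band-limited
#' 1/f background noise, all passed through the day's gain/leakage/noise
#' transform. The same spec (including seed) yields a bit-identical
#' cohort.
#'
#' @param spec a [cohortSpec()].
#' @return named list of [RawSession-class] (`"S01_d1"`, ...), ordered by
#'   subject then day.
#' @examples
#' spec <- cohortSpec(nSubjects = 2, nDays = 1, trialsPerTask = 2, seed = 7)
#' sessions <- generateCohort(spec)
#' sessions[[1]]
#' @export
generateCohort <- function(spec) {
  validateCohortSpec(spec)
  out <- vector("list", spec$nSubjects * spec$nDays)
  nm <- character(length(out))
  k <- 0L
  for (i in seq_len(spec$nSubjects)) {
    fp <- subjectFingerprint(spec, i)
    for (d in seq_len(spec$nDays)) {
      de <- dayEffect(spec, i, d)
      k <- k + 1L
      out[[k]] <- synthSession(spec, fp, de, i, d)
      nm[k] <- sprintf("%s_d%d", fp$subject_id, d)
    }
  }
  names(out) <- nm
  out
}

#' Write / read a session in the plain-text CSV dialect
#'
#' `writeSessionCsv()` writes the continuous samples as CSV preceded by
#' four comment headers (`# subject=`, `# day=`, `# fs=`, `# channels=`),
#' one row per time sample with one column per channel, values rounded to
#' 6 decimal places (microvolts); events go to a companion CSV
#' (`<path minus .csv>_events.csv` by default) with columns
#' `onset_sample,task,arm`. UTF-8, `.` decimal, LF line endings.
#'
#' @param session a [RawSession-class].
#' @param path samples CSV path.
#' @param eventsPath events CSV path; default derived from `path`.
#' @return (write) invisibly, the two paths; (read) a [RawSession-class].
#' @export
writeSessionCsv <- function(session, path, eventsPath = NULL) {
  stopifnot(is(session, "RawSession"))
  validObject(session)
  if (is.null(eventsPath)) eventsPath <- defaultEventsPath(path)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  hdr <- c(
    sprintf("# subject=%s", session@subjectId),
    sprintf("# day=%d", session@dayIndex),
    sprintf("# fs=%.10g", session@samplingRate),
    sprintf("# channels=%s", paste(session@channelNames, collapse = ",")),
    paste(session@channelNames, collapse = ",")
  )
  writeLines(hdr, con, sep = "\n")
  m <- t(session@samples)
  txt <- do.call(paste, c(lapply(seq_len(ncol(m)),
                                 function(j) sprintf("%.6f", m[, j])),
                          sep = ","))
  writeLines(txt, con, sep = "\n")
  utils::write.csv(session@events, eventsPath, row.names = FALSE,
                   quote = FALSE)
  invisible(c(path, eventsPath))
}

defaultEventsPath <- function(path) {
  sub("(\\.[Cc][Ss][Vv])?$", "_events.csv", path)
}

#' @rdname writeSessionCsv
#' @param epochS epoch length (s) recorded on the returned session, used
#'   to validate event windows.
#' @export
readSessionCsv <- function(path, eventsPath = NULL, epochS = 3) {
  if (is.null(eventsPath)) eventsPath <- defaultEventsPath(path)
  lines <- readLines(path, n = 5L)
  parseHdr <- function(i, key) {
    pat <- sprintf("^# %s=(.*)$", key)
    if (i > length(lines) || !grepl(pat, lines[i]))
      stop(sprintf("parse error at %s line %d: expected '# %s=...'",
                   path, i, key), call. = FALSE)
    sub(pat, "\\1", lines[i])
  }
  subject <- parseHdr(1L, "subject")
  day <- suppressWarnings(as.integer(parseHdr(2L, "day")))
  fs <- suppressWarnings(as.numeric(parseHdr(3L, "fs")))
  channels <- strsplit(parseHdr(4L, "channels"), ",", fixed = TRUE)[[1]]
  if (is.na(day) || is.na(fs))
    stop(sprintf("parse error at %s line 2-3: non-numeric day/fs", path),
         call. = FALSE)
  dat <- utils::read.csv(path, skip = 4L, header = TRUE,
                         check.names = FALSE)
  if (ncol(dat) != length(channels))
    stop(sprintf(
      "parse error at %s line 5: %d data columns but %d declared channels",
      path, ncol(dat), length(channels)), call. = FALSE)
  ev <- utils::read.csv(eventsPath, header = TRUE,
                        stringsAsFactors = FALSE)
  if (!all(c("onset_sample", "task", "arm") %in% names(ev)))
    stop(sprintf("parse error at %s line 1: expected header onset_sample,task,arm",
                 eventsPath), call. = FALSE)
  win <- round(epochS * fs)
  bad <- which(ev$onset_sample < 1 | ev$onset_sample + win - 1 > nrow(dat))
  if (length(bad))
    stop(sprintf("parse error at %s line %d: event window outside recording",
                 eventsPath, bad[1] + 1L), call. = FALSE)
  new("RawSession",
      subjectId = subject, dayIndex = day,
      samples = t(as.matrix(dat)), samplingRate = fs,
      channelNames = channels, epochS = epochS,
      events = data.frame(onset_sample = as.integer(ev$onset_sample),
                          task = ev$task, arm = ev$arm,
                          stringsAsFactors = FALSE))
}
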
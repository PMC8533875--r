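# Shared fixtures, all generated in code.

# small, fast learner used throughout the unit tests
tinyLearnerConfig <- function(seed = 1L, epochs = 10L, hiddenUnits = 8L) {
  learnerConfig(hiddenUnits = hiddenUnits, epochs = epochs, batchSize = 8L,
                learningRate = 3e-3, seed = seed)
}

# linearly separable toy set: class 1 sits at +mu, class 0 at -mu
separableSet <- function(nPerClass = 6L, d = 6L, nT = 12L, mu = 1,
                         noise = 0.05, seed = 42L) {
  set.seed(seed)
  feats <- c(
    lapply(seq_len(nPerClass), function(i)
      matrix(mu + rnorm(d * nT, 0, noise), d, nT)),
    lapply(seq_len(nPerClass), function(i)
      matrix(-mu + rnorm(d * nT, 0, noise), d, nT))
  )
  labeledSet(feats, rep(c(1L, 0L), each = nPerClass))
}

# learner with all-zero weights: p_yes is exactly 0.5, so its decision is
# controlled entirely by the threshold -- handy for vote-logic tests
constLearner <- function(decision, d = 3L, h = 2L) {
  stopifnot(decision %in% 0:1)
  cfg <- unclass(tinyLearnerConfig())
  cfg$decisionThreshold <- if (decision == 1L) 0.4 else 0.6
  new("WeakLearner",
      weights = list(
        Wx = matrix(0, 4 * h, d), Wh = matrix(0, 4 * h, h),
        b = numeric(4 * h), Wd = matrix(0, 2, h), bd = c(0, 0)),
      normStats = list(mean = numeric(d), sd = rep(1, d)),
      config = cfg, inputDim = as.integer(d), nFrames = 5L)
}

constEnsemble <- function(decisions) {
  new("BaggedAuthenticator",
      learners = lapply(decisions, constLearner),
      config = list(M = length(decisions), tieRule = "reject"),
      context = list())
}

# memoised small cohorts/pools so several test files can share one build
.fixtures <- new.env(parent = emptyenv())

cachedPool <- function(key, specArgs, ...) {
  if (is.null(.fixtures[[key]])) {
    spec <- do.call(cohortSpec, specArgs)
    .fixtures[[key]] <- buildFeaturePool(generateCohort(spec), ...)
  }
  .fixtures[[key]]
}

smallPool <- function() {
  cachedPool("small", list(nSubjects = 4, nDays = 2, trialsPerTask = 6,
                           seed = 11))
}

# Welch band-power oracle: mean periodogram over 50%-overlapping
# Hann-tapered segments, integrated over [lo, hi) Hz
welchBandPower <- function(x, fs, lo, hi, seg = 256L) {
  starts <- seq(1L, length(x) - seg + 1L, by = seg %/% 2L)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  psd <- rowMeans(vapply(starts, function(s) {
    Mod(fft(x[s:(s + seg - 1L)] * w))^2
  }, numeric(seg)))
  f <- (seq_len(seg) - 1) * fs / seg
  sum(psd[f >= lo & f < hi])
}
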
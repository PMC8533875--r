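---
title: "Chronic EEG authentication with bagged LSTM weak learners: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronic EEG authentication with bagged LSTM weak learners: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neuroauth)
```

## The problem

Brainwave biometrics ask whether a short EEG recording can verify a
claimed identity. The chronic setting — the same person recorded on
several different days with a consumer dry-electrode headset — is the
hard version of the problem: electrode placement, contact quality and
background state drift from day to day, so a verifier trained on one
day's data must generalize across days. `neuroauth` implements a
complete verification pipeline for this setting: motor-task EEG epochs
are reduced to short-time Fourier transform (STFT) sub-band power
sequences, a shallow LSTM acts as a binary Yes/No authenticator, and
bootstrap aggregating (bagging) with majority voting stabilizes the
decision on the small training sets that realistic enrollment permits.
Multiple motor tasks can be combined into one authentication policy to
trade the false acceptance rate (FAR) against the false rejection rate
(FRR).

Because multi-day EEG authentication corpora are not publicly
available, the package ships a first-class synthetic cohort generator
that reproduces the statistical structure the method assumes. All tests
and the acceptance script run against this generator.

## The pipeline

### Preprocessing

Raw sessions (8 channels, 250 Hz) are filtered with an order-4
Butterworth band-pass at 1–30 Hz, downsampled to 100 Hz and cut into
3-s task epochs of 8 × 300 samples.

Two choices here are deliberate design decisions:

* **Zero-phase filtering.** The filter runs forward and backward
  (`signal::filtfilt`), doubling the effective magnitude order but
  cancelling group delay, so the 3-s task window is not shifted. An
  offline pipeline has no reason to accept phase distortion.
* **Whole-session filtering before epoching.** Filtering the continuous
  recording avoids per-epoch edge transients; epochs are cut afterwards.
  The 250 → 100 Hz change is the rational ratio 2/5 and is done by
  polyphase resampling (`signal::resample`); since the signal is already
  band-limited to 30 Hz, the anti-alias dialect is immaterial.

### Features

Each epoch channel is analyzed with a 128-point Hanning-tapered STFT at
nominally 98% overlap. A 98% overlap of 128 samples implies a
non-integer hop of 2.56 samples, which no frame grid realizes; we fix
the hop at 3 samples (overlap 125, ≈ 97.7%) and symmetrically zero-pad
each 300-sample epoch to 330 samples, which makes the frame count
exactly `floor((330 − 128)/3) + 1 = 68`. The one-sided spectrogram is
therefore 65 × 68 with 100/128 = 0.78125 Hz bin spacing. Power is
`20 log10 |X|` dB with magnitudes floored at 1e−12 so silent bins stay
finite.

Bins are grouped into the five mu/beta sub-bands 7–11, 11–16, 16–21,
21–25 and 25–30 Hz by **arithmetic mean of dB values** over member bins
(the aggregation is otherwise unspecified; the mean keeps rows
comparable across bands of different widths). Membership is half-open
`[low, high)` on bin centers so shared band edges are never counted
twice.

Stacking the per-channel 5 × 68 blocks row-wise gives the feature
matrix. Two channel subsets are exposed: `paper_literal` uses the five
central/midline motor-relevant electrodes Fz, C3, Cz, C4, Pz (a 25 × 68
matrix, the smallest stacking consistent with five-channel selection on
this montage); `all_channels` (the default) uses all eight electrodes
(40 × 68).

### The weak learner

The authenticator is deliberately shallow: the feature matrix is
consumed frame by frame by a single LSTM layer, whose final hidden
state feeds a fully connected layer with a two-unit softmax over
{No, Yes} (a symmetric two-class head rather than a single sigmoid
unit).

Hidden size, optimizer, loss, epoch count and normalization are
free parameters of such an architecture; the defaults here are
documented package choices: 64 hidden units, cross-entropy loss, Adam (learning
rate 1e−3), 60 epochs, batch size 8, and per-feature-row z-score
normalization using *training-set* statistics only (dB features have
channel-dependent offsets). Forward pass, backpropagation through time
and Adam run in compiled code (RcppArmadillo); every stochastic choice
(weight initialization, batch shuffling) is drawn from R's RNG under
the configuration seed, so training is bit-reproducible.

The decision is Yes iff `p_yes ≥ decisionThreshold` (default 0.5); the
tie at the threshold accepts, and the convention is documented in
`predictLearner()`.

### Bagging

`M` weak learners (default `M = 9`) are each trained on a bootstrap
resample of the training set — same size, drawn with replacement — and
combined by strict majority vote. Two safeguards:

* **Stratified bootstrap.** A plain bootstrap of a 12-point balanced
  set can produce a single-class, untrainable sample. We resample
  within each class, preserving both the total size and the class
  balance of the original set.
* **Ties reject.** Even `M` can tie the vote. Authentication should
  fail closed, so a tie rejects. (The default `M = 9` and the sweep
  sizes are all odd, so ties only arise in custom configurations.)

### Enrollment and policies

One model is enrolled per subject: for each (task, arm) in the policy,
the positives are all of the subject's training epochs and the
negatives an equal-count random sample of imposter epochs of the same
task — balanced by construction. Two imposter scenarios are supported:
`known_imposters` (negatives from all other subjects, 14 in the default
cohort) and `unseen_imposters` (negatives only from a training group,
e.g. 9 of a 10-subject group, with 5 subjects held out entirely to
model strangers attacking the system).

A multi-task policy accepts only if **every** task's ensemble votes
Yes. Unanimous conjunction is the rule that realizes the intended
trade — combined schemes lower FAR and raise FRR — and that direction
is a theorem under conjunction: the combined false-accept set is the
intersection of the per-task false-accept sets, while the combined
reject set is the union of the per-task reject sets. The rule is an
enum so that threshold or OR rules can be added.

### Evaluation

Leave-one-day-out cross-validation: fold *d* trains on all other days
and tests on day *d*, with arms kept separate. Genuine attempts are the
subject's held-out-day epochs; imposter attempts are all other
subjects' held-out-day epochs (every available test epoch is used
rather than a balanced subsample, so FAR estimates use all the data).
Combined attempts pair same-trial-index epochs across tasks.

FAR = FP/(FP+TN), FRR = FN/(FN+TP), accuracy = (TP+TN)/total — the
standard biometric definitions. Because accuracy depends on how
genuine and imposter attempts are weighted, all four confusion counts
are exported with every result row, so any alternative accuracy
definition can be recomputed from the CSV.

The training-fraction sweep draws a stratified subset of the aggregated
training pool and trains the single LSTM and the bagged ensemble on the
*same* subset (shared subset seed), scoring both on the same fixed test
day; `nRuns` independent draws are averaged (default 5). The
bagging-size sweep repeats the evaluation at each `M`.

Scheme comparisons use a paired two-sided Wilcoxon signed-rank test at
α = 0.05, with zero differences dropped, an exact sign-flip enumeration
of the null for n ≤ 12 (cheap: ≤ 4096 assignments, ties handled through
average ranks) and a tie-corrected normal approximation above.

## The synthetic cohort generator

`generateCohort()` emulates the chronic study design: 15 subjects × 5
days, each session holding 10 performed and 10 imagined motor trials (5
left / 5 right arm, shuffled within task block), 3-s task epochs with a
2-s cue before and 4-s rest after each task, 8 channels at 250 Hz.

The signal model gives each subject the discriminable spectral identity
the method presupposes:

* **Fingerprint.** Per-(channel, sub-band) oscillatory power gains,
  log-normal with sdlog `bandGainDispersion` (default 0.4). This is the
  subject-separability dial: the package asserts (as a property test)
  that downstream authentication accuracy is non-decreasing in it.
* **Task physiology.** Event-related desynchronization (ERD):
  during each task window the oscillatory band power on the central
  channel contralateral to the cued arm (C3 for right, C4 for left) is
  suppressed by `erdDepth` (default 0.5); imagined-movement ERD is 0.7×
  the performed depth, a package choice reflecting weaker imagery
  modulation, not an estimate from data. The ERD envelope has 50-ms
  cosine ramps so the modulation does not splatter energy outside the
  generator band.
* **Background.** 1/f Gaussian noise (exponent 1.0), band-limited to
  45 Hz; the band-limit keeps the whole generator alias-safe for the
  downstream resample and keeps the oracle PSD analytic.
* **Day effects.** Per-channel log-normal gain jitter, a row-stochastic
  channel-leakage mixing matrix (off-diagonal mass 0.05, a surrogate
  for slightly different electrode placement), and a log-normal
  noise-scale factor.

One global seed drives everything through a splitmix-style sub-seed
derivation (`mixSeed()`), so each subject, day and stage has an
independent stream and the whole cohort is bit-reproducible.

No effect-size information exists for real inter-subject separability,
so the generator's defaults are free parameters chosen once to be
plausible for sensorimotor EEG — oscillation-to-background power ratio
of roughly 20:1 inside a sub-band, ~10% day-to-day gain jitter. What
passing tests show is therefore that the *method* behaves as claimed on
data with this structure (ERD present, stable spectral identity,
day-level nuisance variation); they cannot show that real EEG carries
this much identity information. The generator also omits ocular/muscle
artifacts, electrode pops and non-stationarity within a session.

## Numerical and scale choices

* dB floor 1e−12; z-score sd floor 1e−8; both only guard degenerate
  silent inputs.
* `resampleToTarget` trims or zero-pads at most one trailing sample to
  meet the contracted length `round(n · target/rate)`.
* The test suite and the acceptance script run the evaluation at a
  reduced learner (16 hidden units, 12 epochs, learning rate 3e−3) —
  chosen once as the package's evaluation scale so that a full
  15-subject × 5-day leave-one-day-out pass with `M = 9` trains its
  ~1350 networks in a few minutes on one CPU. The ensemble-size
  comparison (M = 1 vs 9, three seeds) runs on an 8-subject × 3-day
  sub-cohort for the same reason. At these settings the default
  synthetic cohort yields single-task accuracies around 0.98 with FAR
  near 0.02, and the combined policy drives FAR an order of magnitude
  lower while FRR rises — the qualitative FAR/FRR trade the method is
  designed around.

## Known limitations

* The LSTM trainer is plain full-BPTT Adam without gradient clipping or
  early stopping; it is adequate at the package's data scale but not a
  general-purpose deep-learning engine.
* `paper_literal` mode fixes the five-channel subset by montage
  plausibility; `all_channels` is the default and the recommended mode
  for new experiments.
* Statistical comparisons assume per-subject means are exchangeable
  pairs; with 15 subjects the exact signed-rank path is always taken.
* The synthetic cohort is a model of the study design, not of any real
  recording; absolute performance numbers on it are not comparable to
  numbers on real data.
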
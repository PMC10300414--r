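---
title: "Spectral sleep staging and apnea screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral sleep staging and apnea screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sleepstager` implements an integrated analysis chain for overnight sleep
EEG: per-epoch spectral feature extraction, five-class sleep staging with
three classical learning algorithms, and obstructive sleep apnea (OSA)
screening from stage-conditioned feature averages.  This vignette is the
package's own account of the method: the model, its assumptions, every
tunable that matters, and the design choices made where the procedure was
genuinely open.

## The feature model

The atomic unit is the 30-second scoring epoch, the convention under which
human experts assign one of five stages (W, N1, N2, N3, R) to each epoch.
Six scalp channels are used (F3, F4, C3, C4, O1, O2; international 10--20
placement) at a sampling rate of 200 Hz.  Preprocessing is deliberately
minimal -- a 0.5--50 Hz zero-phase Butterworth bandpass -- because common
EEG artifacts themselves carry stage information and aggressive cleaning
is a cost best avoided in a screening tool.

Each epoch channel is transformed with a short-time Fourier transform:
1-second windows, 50% overlap, so a 30-s epoch yields exactly 59 windows,
with 1 Hz frequency resolution (no zero-padding).  Each window's power
spectrum is divided by its own total power over 0.5--50 Hz ("relative
PSD"), which makes every downstream feature invariant to signal amplitude
-- an important property given inter-subject and inter-lab gain
differences.

Six bands are scored: low delta (0.5--2 Hz), delta (1--4), theta (4--8),
alpha (8--12), sigma (12--15) and beta (15--30 Hz).  Low delta and delta
overlap deliberately: slow-wave activity and K-complex energy occupy
partially overlapping ranges.  Eight features summarise each channel:

* mean relative power over the 59 windows in low delta, theta, alpha and
  beta;
* `K_comp_1` = the *maximum* delta-band fraction over the 59 windows and
  `K_comp_2` = the mean of the remaining 58.  A K-complex is a large
  0.5--1.5 s biphasic transient: it inflates the delta fraction of the one
  window containing it, so the max-vs-rest split separates "one big
  transient" from "sustained slow activity";
* `spindle_1`/`spindle_2`, the same max / mean-of-rest pair on the sigma
  band, targeting sleep spindles (brief 12--15 Hz bursts).

Eight features x six channels = 48 features per epoch.  Per-subject
screening profiles average these vectors over REM epochs and over pooled
NREM (N1 + N2 + N3) epochs -- 96 values, optionally extended by one
oximetry scalar (SpO2, percent saturation).

### Numerical conventions

Choices the feature definition leaves open are pinned as follows and used
identically by the test oracles:

* STFT taper: periodic Hann window; power is the squared magnitude of the
  tapered window's DFT.
* Band membership of a 1 Hz bin `f` is half-open upper-inclusive,
  `low < f <= high` (delta = bins {2, 3, 4} Hz).
* The normalization denominator is the 0.5--50 Hz range, matching the
  preprocessing band; bins outside it are zeroed.
* "Mean of the remaining 58" excludes the argmax window; ties break to
  the lowest window index.
* A window with zero in-range power (possible for degenerate synthetic
  inputs) gets relative value 0 and is flagged; an all-zero epoch is an
  error, since its relative PSD is undefined.
* The bandpass is a 4th-order Butterworth design applied
  forward-backward (zero-phase), so transient waveforms are not
  phase-distorted; the two-pass filter squares the magnitude response,
  giving roughly 39 dB attenuation at 80 Hz while passband frequencies
  are preserved within a few percent.

## Classifiers and model selection

Three estimators are trained on identical inputs: an RBF-kernel support
vector machine, k-nearest neighbours, and a multilayer perceptron.
Hyperparameters come from fixed grids searched by stratified 3-fold
cross-validation *inside* each training set (selection by mean accuracy,
ties to the first-listed candidate), then the winner is refitted on the
full training set:

| algorithm | grid | size |
|---|---|---|
| svm | C in {0.1, 1, 10, 100} x gamma in {0.001, 0.01, 0.1, 1, 10} | 20 |
| knn | k in {1, 3, ..., 19} x weights {uniform, distance} x metric {euclidean, manhattan} | 40 |
| mlp | 1--2 hidden layers, nodes per layer in {16, 32, 64}, chosen independently | 12 |

Features are z-scored with training-set statistics only; the scaler is
stored in the fitted model and re-applied at prediction time, so no
held-out information ever enters the standardization.  The MLP uses ReLU
activations, a softmax cross-entropy output, and minibatch Adam
(learning rate 1e-3, batch 200, at most 200 epochs with loss-based early
stopping); weights are Glorot-initialized from a seeded stream, making
every fit reproducible.  The kNN predictor implements both vote-weight
schemes and both Minkowski metrics with deterministic tie-breaking
(nearer neighbour first, then lower training index; vote ties resolve to
the earlier class in canonical order).

Two open points were decided as package policy: model selection uses a
*nested* (inner) split rather than reusing the outer evaluation folds,
preventing selection leakage at modest extra cost; and no class
rebalancing is applied by default, since overnight stage distributions
are naturally skewed and a screener should be calibrated to them.

## Validation harness

`repeated_cv()` runs the canonical protocol: 10 repetitions of 5-fold
cross-validation, each repetition on a freshly shuffled partition,
yielding 50 held-out accuracy values plus per-stage one-vs-rest F1 and a
summed confusion matrix.  Two splitting units are first-class: `epoch`
(folds stratified by stage) and `subject` (whole subjects per fold,
stratified by age group x severity; no subject ever straddles a fold
boundary).  Which unit the original protocol used is not derivable from
the procedure description, so both are implemented and recorded in the
result's config; `subject` is the default because it is the honest
deployment scenario.  F1 for a stage absent from both truth and
prediction is recorded as undefined (`NA`) and excluded from averages
rather than zero-filled, so short recordings are not penalized for
missing N3.

Model variants are compared by classical one-way ANOVA (between/within
sums of squares, df = groups - 1 and total - groups) at significance
0.01, followed -- only when the omnibus test is significant -- by
pairwise pooled-variance t-tests with Bonferroni correction.  Constant
input with equal means is defined to give F = 0.

## OSA screening and the integrated pipeline

The screener is trained on per-subject profiles (96 REM/NREM means, plus
SpO2 when enabled) with the same grids and scaler policy.  Two class
sets exist: the three-class problem (healthy / mild-to-moderate /
severe) and the binary healthy-vs-severe problem, which excludes the
intermediate group whose profiles overlap both ends.  The *deployed*
screener is the healthy-vs-severe model applied to all comers as a
healthy-vs-OSA decision, mirroring the screening protocol it
implements; NREM aggregation pools epochs rather than averaging
per-stage means (the simplest consistent reading; a per-stage-mean
variant would weight sparse N3 equally with abundant N2).

`integrated_screen()` composes the full deployment path: bandpass ->
segment -> featurize -> *predicted* hypnogram -> profile over predicted
REM/NREM -> screening decision.  With a perfect staging oracle this is
bitwise identical to expert-stage screening (asserted in tests).  Edge
policies: a predicted hypnogram with no REM (common in short recordings)
has the missing aggregate imputed with the training-population mean and
warns; an all-wake prediction returns an explicit `"unscreenable"`
outcome instead of a guess.  SpO2 enters as whatever scalar the metadata
supplies -- the package does not commit to mean versus minimum
saturation, which the source demographics do not disambiguate.

## The synthetic cohort generator

No clinical recordings ship with the package; the generator exists so
every stage of the pipeline is testable end-to-end with known ground
truth.  Per stage it mixes band-limited Gaussian noise to target
relative band-power fractions (alpha-dominant wake, theta-dominant N1,
K-complex + spindle N2, slow-wave N3, mixed-frequency REM, following the
standard stage descriptions), synthesized in the frequency domain and
scaled so transient amplitudes are expressed in background-SD units.
The six channels share 80% of their variance with 20% independent noise
-- informative but not redundant.  N2 epochs receive K-complex
surrogates (Hann-windowed biphasic transients with a 2 Hz carrier, so
their energy falls inside the 1--4 Hz delta band the max operator
scores; default 4x background SD) and spindle surrogates
(Hann-enveloped 13.5 Hz bursts, 3x) at 0.5 events/epoch each -- one
roughly every two epochs -- with durations uniform on 0.5--1.5 s.  The
N2 background keeps its slow-wave fraction below 20% (the criterion
separating it from N3), so N2's delta signature is carried by the
transients, as in real recordings.  Hypnograms follow a first-order Markov
chain with strong self-transitions.

Severity effects are multiplicative template shifts in the reported
qualitative directions: K-complex amplitude and rate *down* with
severity (x0.8 mild-to-moderate, x0.55 severe), beta background power
*up* (x1.25, x1.6), sigma mildly up.  No quantitative effect sizes are
available to calibrate against, so these defaults were chosen once to
produce clearly detectable but not trivial group differences, and are
labelled synthetic throughout.  Per-subject variability is a log-normal
jitter (SD 0.15) on band powers and event amplitudes, applied once per
subject.  Oximetry is drawn per age x severity cell from normal
distributions with the clinical demographic parameters (e.g. healthy
younger 89.4 +/- 8.1, severe younger 73.4 +/- 11.0), truncated to
(0, 100].

What the generator does *not* emulate: 1/f spectral slopes, artifacts,
arousals, stage-transition microstructure, respiration or airflow
channels, and realistic overlap between N1 and REM.  Passing recovery
tests therefore demonstrates that the pipeline's machinery is correct
and sensitive to the encoded structure -- not that clinical accuracy
levels would be reproduced on hospital data, which are substantially
harder (the per-stage feature distributions of real EEG overlap far
more than these templates do).

## Problem sizes used by the test suite

The packaged experiments are sized for a single CPU: the staging cohort
is 30 subjects (5 per age x severity cell) x 200 epochs with a
one-subject-per-cell holdout; the screening cohort is 60 healthy + 60
severe subjects x 40 epochs with 20 held out; effect-direction checks
use 25 subjects per class x 30 epochs.  Feature invariants are asserted
over 1000 randomized epochs and event-detection monotonicity over 200
paired epochs per transient type.

## Known limitations

* Epoch-independent classification cannot use scoring context (an N2
  epoch following N2 is scored N2 even without a spindle or K-complex),
  which caps N1 performance in principle.
* The MLP is a compact in-package implementation (full grids, Adam,
  ReLU); it is deterministic and adequate for 48--96 dimensional
  features but not a deep-learning substitute.
* Recordings are read from the package's documented float64+JSON
  sidecar format; EDF export from acquisition software must be converted
  upstream.
* SpO2 is a single scalar per subject; no time-resolved oximetry is
  modelled.

## Reproducing a run

```{r example}
library(sleepstager)
cohort <- simulate_cohort(cohort_spec(n_per_cell = 3, epochs_per_subject = 60,
                                      seed = 1))
feats <- featurize_cohort(cohort)
model <- fit_staging_model(feats, "svm", seed = 1)
glance(model)
cv <- repeated_cv(feats, "knn", k = 5, reps = 2, seed = 1, meta = cohort$meta)
glance(cv)
autoplot(cv)
```
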
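# sleepstager

Automatic sleep staging and obstructive sleep apnea (OSA) screening from
multichannel sleep EEG, for sleep researchers and engineers building
EEG-only screening tools.  The package implements the full chain from
raw signal to screening decision -- spectral feature extraction,
five-class stage classification, stage-conditioned subject profiling,
and a repeated cross-validation / ANOVA evaluation harness -- together
with a seeded synthetic polysomnography generator, so every component is
testable end-to-end without clinical recordings.

## The method

**Features.**  Six channels (F3, F4, C3, C4, O1, O2; 200 Hz) are
bandpassed to 0.5–50 Hz (4th-order Butterworth, zero phase) and cut into
30-s epochs.  Each epoch channel gets a short-time Fourier transform
with 1-s Hann windows at 50% overlap — 59 windows per epoch, 1 Hz bins.
Each window's power spectrum *P(f)* is normalized by its own total over
0.5–50 Hz, giving the relative PSD *p(f) = P(f) / Σ P(f)*, which is
amplitude-invariant.  With band fractions
*b<sub>w</sub> = Σ<sub>f∈band</sub> p<sub>w</sub>(f)* over windows
*w = 1…59*, each channel contributes eight features:

| feature | definition |
|---|---|
| `low_delta`, `theta`, `alpha`, `beta` | mean of *b<sub>w</sub>* over the 59 windows (bands 0.5–2, 4–8, 8–12, 15–30 Hz) |
| `K_comp_1` | max over windows of the delta (1–4 Hz) fraction — sensitive to a K-complex transient |
| `K_comp_2` | mean of the remaining 58 delta fractions |
| `spindle_1`, `spindle_2` | the same max / mean-of-rest pair on sigma (12–15 Hz) — sleep spindles |

8 features × 6 channels = 48 per epoch.

**Staging.**  Three classifiers — RBF-kernel SVM, kNN, and a multilayer
perceptron (ReLU, Adam, ≤200 iterations) — are trained on the 48
features with z-scoring from training data only and hyperparameters
selected by inner 3-fold cross-validated grid search (SVM: C ∈ {0.1, 1,
10, 100} × γ ∈ {0.001, …, 10}; kNN: k ∈ {1, 3, …, 19} × weights ×
metric; MLP: 1–2 hidden layers × {16, 32, 64} nodes).

**Screening.**  Per subject, the 48-vectors are averaged over REM epochs
and over pooled NREM epochs (96 features, +1 optional SpO₂ scalar).  The
deployed screener is trained healthy-vs-severe and applied to all comers
as a healthy-vs-OSA decision; `integrated_screen()` runs the whole
pipeline on a raw recording using *predicted* stages.

**Evaluation.**  `repeated_cv()` gives 10 × 5-fold accuracies (50
values), per-stage F1 and confusion matrices, with epoch- or
subject-level folds; `one_way_anova()` compares model variants with
Bonferroni post-hoc t-tests at p < 0.01.

## Worked example

```r
library(sleepstager)

# a small synthetic cohort: 12 subjects (2 per age x severity cell), 60 epochs
cohort <- simulate_cohort(cohort_spec(n_per_cell = 2, epochs_per_subject = 60,
                                      seed = 1))
feats  <- featurize_cohort(cohort)          # 720 epochs x 48 features

train  <- feats[feats$subject_id != "Sy_he_01", ]
test   <- feats[feats$subject_id == "Sy_he_01", ]
model  <- fit_staging_model(train, "svm", seed = 1)
model
#> <sleep_model> svm (C=1, gamma=0.1): 660 training rows, classes [W,N1,N2,N3,R]

hyp <- predict_stages(model, test)          # the held-out subject's hypnogram
stage_metrics(test$stage, hyp$stage)
#> <stage_metrics> accuracy 0.917; f1: W=1.000 N1=0.545 N2=1.000 N3=1.000 R=0.889
```

The grid search selected C = 1, γ = 0.1 with 0.977 inner-CV accuracy;
on the held-out subject 55 of 60 epochs are staged correctly (all five
errors are REM scored as N1 — the classic shallow-sleep confusion).
`autoplot(hyp)` draws the hypnogram; `tidy(model)` lists all 20 grid
candidates with their inner-CV accuracies.

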
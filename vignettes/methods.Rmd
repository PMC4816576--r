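---
title: "Simulating and decoding error-related EEG components: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding error-related EEG components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(errclass)
```

## The problem

When people commit a response error, the response-locked EEG shows two
characteristic deflections: a fronto-central **error negativity** (Ne, also
called ERN) peaking roughly 70 ms after the button press and maximal near
FCz, and a centro-parietal **error positivity** (Pe) around 200–250 ms,
maximal near Cz and linked to error awareness. Both are visible in single
trials, which makes response correctness decodable from the EEG: extract
windowed mean amplitudes around the two components, train a classifier on
a subject's labeled trials, and predict error vs. correct on held-out
trials — within one task, or across two functionally different tasks
(a speeded flanker task and a mental rotation task) if error monitoring is
task-general.

`errclass` implements this full analysis as tested code: a synthetic
cohort generator, preprocessing, ERP statistics, feature extraction, and
an RBF-SVM classification scheme with nested grid search, stratified
10-fold cross-validation, cross-task transfer and permutation-based
significance. Because no real recordings ship with the package, the
generator is the data source for every analysis; its defaults encode the
study conditions the pipeline is meant to operate under.

## The generative model

Each simulated trial at channel $c$ and time $t$ (ms, response-locked) is

$$x_{c}(t) = \sum_{k \in \{\mathrm{Ne},\mathrm{Pe}\}} s_k\, a_k(y)\,
  \exp\!\left(-\frac{d_c^2}{2\sigma_k^2}\right)
  \exp\!\left(-\frac{(t-\mu_k)^2}{2 w_k^2}\right) + \varepsilon_c(t),$$

where $y$ is the trial's response label, $a_k(y)$ the component's peak
amplitude on error or correct trials, $d_c$ the schematic montage distance
of channel $c$ from the component's peak channel (FCz for Ne, Cz for Pe),
and $s_k$ a per-subject lognormal scaling factor. The noise
$\varepsilon$ is the sum of white noise, 1/f-shaped ("pink") background
synthesized in the frequency domain, and an optional 10 Hz rhythm with
random phase per trial and channel.

Modelling choices, where the underlying phenomenon does not dictate a
form:

* **Gaussian bump in time.** ERP components are unimodal and roughly
  symmetric at this time scale; a Gaussian with peak latency `mu` and SD
  `width` is the simplest shape with interpretable parameters (Ne: 70/25
  ms, Pe: 220/35 ms).
* **Isotropic Gaussian topography.** Scalp maps of both components are
  single-peaked blobs; an isotropic falloff over 2-D montage distance
  (`spatial_sigma` 0.45/0.5 in head-radius units) reproduces that
  structure without volume conduction modelling.
* **Multiplicative lognormal between-subject scaling** (`sdlog = 0.3`,
  mean 1 by construction), shared across both tasks per component, so
  that per-subject classifiability varies coherently — some simulated
  subjects are "good decoders" in both tasks, as real per-subject report
  tables show.
* **Correct-trial activity is not zero.** The Ne has a correct-response
  analog (CRN); correct trials carry a small bump of the same shape
  (−3 μV peak for the Ne analog, +0.5 μV for the Pe), and error trials
  differ by a calibrated amount.
* **Reaction times** are Gaussian, truncated to (100, 1000) ms — the
  analysis-side exclusion window — with task/response-specific means
  (242/311 ms flanker error/correct, 436/446 ms rotation) and SDs of
  50/90 ms. Only means are constrained by the conditions the package
  targets; the SDs are plausible round values.
* **Errors are i.i.d. Bernoulli** per trial (13.87% flanker, 17.67%
  rotation). Sequential structure (post-error slowing etc.) is
  deliberately out of scope.

## Calibration of the shipped defaults

Two quantities anchor the effect sizes: the error-minus-correct windowed
mean difference at FCz in 20–100 ms (Ne) and at Cz in 180–250 ms (Pe),
averaged over the two tasks, are calibrated to **10.15 μV** and
**3.97 μV**, with the flanker task above and the rotation task below the
mean (13.0/7.3 μV and 5.5/2.44 μV) so that the task × accuracy
interaction points the right way. The calibration inverts the closed-form
windowed mean of the Gaussian bump — evaluated on the discrete 500 Hz
sampling grid, so the pipeline's estimand is centered exactly on the
targets; `gaussian_window_factor()` exposes both the continuous and the
discrete factor, and `expected_window_difference()` returns the implied
expectation for any configuration.

The noise levels are free parameters of the simulator, not measurable
from any shipped data; they were calibrated once so that the *pipeline's
own* within-task combined-feature CV accuracies land in realistic
single-trial decoding ranges — a mean near 85% for the easier flanker
task and near 75% for the rotation task, with per-subject spread of
roughly ±10 points. The shipped values are `white_sd = 15`,
`pink_sd = 14`, `alpha_sd = 4` μV. This makes the accuracy-band checks a
joint test of the calibrated simulator and the classification code, not a
claim about real recordings.

Trial counts are desk-scaled: `n_trials_range = c(100, 260)` per subject
and task keeps a 200-subject cohort simulation in the minutes range while
preserving the error-rate structure and the ordering of per-subject error
counts between tasks. The acceptance checks and analysis scripts state
the cohort sizes they use (200 subjects for effect recovery, 10 for the
classification bands, 20 for the structural report check).

## Preprocessing

* **Filter:** linear-phase FIR band-pass, 0.5–25 Hz (Hamming design,
  order 166 at 500 Hz), applied per trial and channel by FFT convolution
  with reflection padding and group-delay compensation — the realized
  response is zero-phase. `filter_gain()` reports the realized amplitude
  response; at the defaults the 10 Hz gain is within 1 dB of unity and
  50 Hz is attenuated by well over 20 dB.
* **Re-reference:** average of M1/M2 subtracted from every channel.
* **Artifact rejection:** one pooled distribution over all trials, EEG
  channels and samples; a trial is flagged if any point exceeds 3 pooled
  SDs, and at most 5% of trials are removed — if more are flagged, those
  with the largest within-trial |z| go first, ties broken by lower trial
  index. Auxiliary channels (mastoids, EOG) are excluded from the pooled
  statistics; a zero-SD (constant) input rejects nothing. Ocular ICA
  cleaning is intentionally a no-op hook (`ocular_hook` in
  `preprocess_epochs()`): the simulator generates no ocular artifacts and
  ICA algorithms are external tools.
* **Epoch window:** −200…+798 ms response-locked (500 samples at 500 Hz);
  both measurement windows must lie inside the epoch, which the
  configuration validates. No baseline correction is applied anywhere.

## Classification scheme

Features are windowed mean voltages at five electrodes per component
(Ne: Fz, FCz, FC1, FC2, Cz over 20–100 ms; Pe: Cz, FCz, CPz, C1, C2 over
180–250 ms; combined: all ten). Classes are balanced by keeping every
error trial and a seeded random sample of equally many correct trials;
the balanced set is the analysis universe, and each of the (by default
10) repeats re-draws it.

The classifier is a soft-margin RBF-SVM. Hyperparameters come from a
nested grid search — coarse grid $C \in 2^{-5..15}$ (step $2^2$),
$\gamma \in 2^{-15..3}$ (step $2^2$), then a fine grid spanning ±2 powers
of 2 around the coarse optimum in half-power steps — each point scored by
stratified 10-fold CV with the same fold assignment, ties broken toward
smaller $C$, then smaller $\gamma$. Feature scaling to [0, 1] is fit on
each fold's training part only (out-of-range values clip); fitting one
scaler on the whole set before splitting — a common shortcut — is
available as `scale_jointly = TRUE` for comparability, at the cost of a
mild information leak. Cross-task transfer selects hyperparameters on
the training task, refits scaler and SVM on its full balanced set, and
classifies the other task's balanced trials scaled with the training
scaler.

Significance uses a randomization test: class labels are permuted (1000
times at full scale) and the accuracy recomputed. Within-task, each
permutation re-runs the *entire* CV procedure — fold stratification and
per-fold scaler fits included — at the selected hyperparameters. This
detail is load-bearing: if the observed (label-stratified) folds are
frozen and only the labels permuted, the permuted accuracies are
computed under broken stratification, which on small balanced sets
biases CV accuracy below chance (the training part of each fold is then
imbalanced *against* the held-out labels), shifts the null distribution
down, and makes the test wildly anti-conservative — we measured type-I
error near 50% at nominal α = 0.05 before adopting the re-stratified
scheme, and ~4% after. For transfer, the trained model is fixed and its
predictions are scored against permuted test labels, which involves no
refitting. The p-value is the plain proportion of permuted accuracies at
or above the observed one, which can legitimately be zero; an add-one
estimator is available behind a flag.

Hyperparameters are *not* re-searched per permutation — a computational
choice that keeps the null distribution centered but ignores the
selection step, so the within-task observed statistic (a grid maximum)
is mildly optimistic against its own null. The package's
null-calibration check therefore evaluates the permutation machinery
around a fixed-hyperparameter CV accuracy; replaying the selection
exactly would require a nested grid search inside every permutation,
which the `evaluation` closure of `permutation_pvalue()` permits where
the cost is acceptable.

## Numerical and degenerate-input conventions

* Windowed means include both endpoints on the discrete grid.
* Constant features scale to 0.5; transfer features clip to [0, 1].
* The 2×2 repeated-measures ANOVA is computed from subject-level
  contrasts (F = squared paired t, df (1, n−1),
  $\eta_p^2 = F/(F + n - 1)$); a zero-variance contrast yields F = 0 when
  its mean is zero and F = ∞ otherwise.
* Bootstrap t-tests resample mean-centered paired differences and use
  the add-one p-value; Cohen's d for repeated measures is
  mean(diff)/SD(diff).
* Cohort seeds derive deterministically from one master seed
  (`derive_seed()`), so every report is bit-reproducible; balanced
  resampling, fold assignment and permutations each use their own
  derived stream.
* Degenerate label draws in tiny simulations (all trials one class) are
  repaired by flipping one trial, so downstream stages always see both
  classes.

## What the synthetic data do and do not show

The generator reproduces the statistical skeleton the analysis relies
on: two unimodal components with the right latencies, topographic peaks,
effect sizes and task attenuation; realistic error rates, RT structure
and trial-count imbalance; 1/f-dominated background noise; and
between-subject variability in decodability. It does **not** contain
ocular or muscle artifacts, volume-conducted source mixtures,
stimulus-locked components, sequential dependencies, or non-stationary
arousal effects. Green tests therefore certify that the pipeline
recovers what the model puts in, under honest cross-validation and
calibrated significance — they do not certify performance on real
recordings, where preprocessing quality and artifact structure dominate.

## Known limitations

* The EEGLAB `.set` reader is not implemented (MATLAB v5 container);
  BrainVision and the internal container are.
* The permutation scheme holds hyperparameters fixed (see above); the
  within-task observed statistic is a grid-maximum and is therefore
  optimistically biased relative to its own permutation null. With
  informative signal this is immaterial; near chance it makes the test
  anti-conservative, which is why significance claims at chance-level
  accuracies should rely on the fixed-hyperparameter variant.
* The ERP image normalizes by the per-subject maximum absolute value;
  other conventions (z-scoring, percentile clipping) would change its
  appearance but nothing downstream.
* Under the shipped calibration the Pe feature set decodes worse
  (~60–65%) than reported for real recordings, where Pe-only accuracy
  rivals Ne-only. With homogeneous background noise, a component's
  single-trial SNR is pinned by its ERP-level windowed difference, and
  the Pe difference (3.97 μV task mean) is ~2.5× smaller than the Ne's;
  real Pe decodability evidently rests on single-trial structure (e.g.
  lower late-window variance) that this noise model does not represent.
  Combined features consequently tie with Ne-only under the defaults;
  the combined-beats-both property is exercised under a configuration
  in which both components are comparably informative.
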
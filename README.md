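# errclass

Single-trial classification of response correctness (error vs. correct)
from error-related EEG components, as a tested R pipeline.

## Scientific background

Response errors in speeded tasks elicit two well-characterized
deflections in the response-locked EEG: the **error negativity**
(Ne/ERN), a fronto-central negativity peaking ~70 ms after the response
and maximal near FCz, and the **error positivity** (Pe), a
centro-parietal positivity around 200–250 ms, maximal near Cz. Both are
large enough to be visible in single trials, so a subject's response
correctness can be decoded from them — within one task, and, to the
extent that error monitoring is task-general, even across different
tasks (here: a flanker task and a mental rotation task).

The package implements the complete analysis:

* **Synthetic cohort generator** — response-locked 63-channel epochs at
  500 Hz with Gaussian-bump Ne/Pe components, calibrated so the windowed
  mean error−correct differences average 10.15 μV (Ne, 20–100 ms at FCz)
  and 3.97 μV (Pe, 180–250 ms at Cz) across tasks, attenuated in the
  rotation task; error rates 13.87%/17.67%; RT means 242/311 and
  436/446 ms; 1/f + white + 10 Hz background noise; lognormal
  between-subject amplitude scaling.
* **Preprocessing** — zero-phase FIR band-pass (0.5–25 Hz),
  linked-mastoid re-reference, RT exclusion (100–1000 ms), and
  statistical artifact rejection (trials with any point beyond 3 pooled
  SDs, at most 5% removed).
* **ERP statistics** — windowed mean amplitudes, 2×2 repeated-measures
  ANOVAs (F equals the squared paired t; df (1, n−1); partial η²),
  paired bootstrap t-tests, repeated-measures Cohen's d,
  Benjamini–Yekutieli FDR adjustment, RT-sorted ERP images (moving
  average across trials, MA = 40).
* **Classification** — features are windowed mean voltages at five
  electrodes per component (Ne: Fz, FCz, FC1, FC2, Cz; Pe: Cz, FCz, CPz,
  C1, C2; combined: 10 features), linearly scaled to [0, 1] (fit on
  training data only), classes balanced by seeded subsampling of correct
  trials. An RBF-SVM is tuned by nested (coarse→fine) grid search over
  (C, γ) under stratified 10-fold CV, transferred across tasks with the
  selected parameters, tested by label-permutation (p = proportion of
  permuted accuracies ≥ observed), and the whole scheme is repeated over
  fresh balanced samples with mean/min/max aggregation into per-subject
  report tables (7 columns within-task, 11 columns for transfer).

## Worked example

```r
library(errclass)

cfg <- make_default_config(n_subjects = 10)

# one subject, both tasks: simulate, clean, classify
eps <- list()
for (k in 1:2) {
  tk <- cfg$tasks[[k]]
  ep <- simulate_subject(cfg, 1, tk, seed = derive_seed(cfg$seed, 1, k))
  eps[[tk$name]] <- preprocess_epochs(rt_filter(ep))$epochs
}

# within-task decoding of the flanker task, combined Ne+Pe features
rep <- repeat_and_aggregate(eps, feature_set_spec("combined"),
                            mode = "within-flanker", n_repeats = 3,
                            master_seed = 1, n_perm = 200)
rep
#> <classification_report> subject 1, combined features, within-flanker
#>   accuracy 76.67% [76.67, 76.67], p 0.000 [0.000, 0.000], 3 repeats

# cross-task transfer: train on flanker, classify rotation
tr <- repeat_and_aggregate(eps, feature_set_spec("combined"),
                           mode = "flanker->rotation", n_repeats = 3,
                           master_seed = 1, n_perm = 200)
tr
#> <classification_report> subject 1, combined features, flanker->rotation
#>   accuracy 63.33% [62.50, 65.00], p 0.108 [0.070, 0.155], 3 repeats
```

The within-task accuracy (76.7% for this subject) is the pooled 10-fold
CV accuracy at the grid-selected (C, γ), averaged over three balanced
correct-trial samples; the permutation p of 0 means no permutation of
the labels reached the observed accuracy. The transfer accuracy (63.3%)
is the fraction of the rotation task's balanced trials correctly
classified by the SVM trained on the flanker task — above the 50%
chance level of a balanced two-class problem, though for this subject
the permutation test (mean p = 0.108 over repeats) leaves it short of
significance, as happens for a minority of subjects.

The numbered scripts under `analysis/` run the full workflow and write
their tables under `results/`: `01_simulate.R` (cohort + persisted
epochs), `02_preprocess.R` (filter/re-reference/rejection stage counts),
`03_erp_stats.R` (condition table, ANOVAs, error-rate bootstrap test,
ERP image), `04_classify.R` (the twelve per-subject report tables, 4
modes × 3 feature sets).

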
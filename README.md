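# ecgbench

Benchmarking arrhythmia classification from single-lead ECG, with the
bookkeeping that makes such benchmarks comparable: a label dictionary
that unifies dataset-specific annotation symbols, explicit segmentation
rules with label voting, patient-aware cross-validation, and imbalance-
robust evaluation. The package is aimed at researchers who want to
compare segmentation strategies, network architectures and evaluation
schemes under identical, leakage-free conditions — and at anyone who
needs a self-contained, download-free testbed for ECG classification
pipelines.

## What it does

* **Unified labels.** A CSV dictionary maps `(dataset, raw symbol, kind)`
  to unified arrhythmia codes (`AFIB` and `AF` both become `AFIB`);
  tasks group codes into ordered classes — shipped tasks are AAMI-style
  beat form (N / SVEB / VEB), six-class rhythm, and AFIB vs SINUS vs
  other.
* **Both dataset categories.** Beat-level WFDB-style records (text
  headers, 16-bit signals, MIT-format annotation streams with beat
  symbols and `+` rhythm change-points) and recording-level datasets
  (signal files plus a `labels.csv` table).
* **Four segmentations.** R-peak-centred heartbeat windows (`beats0.72s`,
  `beats2.4s`), rhythm episodes, sliding windows (`windows2.5s`,
  `windows10s`) with voting — coverage voting for rhythm tasks,
  abnormal-priority for form tasks — and whole-sequence input
  (`sequence10s`), plus majority-vote aggregation of window predictions
  back to recordings.
* **Patient-aware evaluation.** Inter-patient stratified-group k-fold
  cross-validation (greedy stratification of patients over per-class
  segment counts), intra-patient CV, leave-one-patient-out, holdout and
  predefined folds, with a hard `verify_inter_patient()` guard.
* **Four 1-D neural architectures** — CNN (360 Hz), ResNet (250 Hz),
  GRUAttNet (500 Hz), RTA-CNN (300 Hz) — plus a majority-class
  baseline, trained with Adam and early stopping on a compact built-in
  reverse-mode engine (base R + BLAS; no external deep-learning
  dependency).
* **A synthetic ECG generator** producing annotated datasets of both
  categories (Gaussian-bump beat morphologies, clinically conventional
  RR models, irregular log-normal RR for AFIB), so everything above runs
  end-to-end without downloads.

Evaluation is macro F1: the unweighted mean over classes of
F1 = 2PR/(P+R), computed per cross-validation fold and averaged — the
standard choice when the normal class dominates.

## Worked example

```r
library(ecgbench)

# a 10-patient annotated beat-level dataset, written as WFDB-style files
dir <- file.path(tempdir(), "demo")
h <- generate_beat_level_dataset(
  generator_config(n_patients = 10, record_duration_s = 40, seed = 808,
                   class_mixture = c(SINUS = 0.5, AFIB = 0.3, STACH = 0.2)),
  dir)
h
#> ECG dataset 'synth' (beat_level): 10 records, 10 patients

# AFIB vs SINUS vs other rhythms, 2.5 s sliding windows, CNN,
# 3-fold inter-patient cross-validation
cfg <- experiment_config(dir, dataset_name = "synth",
                         task = "rhythm_reduced", transform = "windows2.5s",
                         architecture = "cnn", eval_scheme = "inter_cv",
                         k = 3, train = train_config(max_epochs = 3),
                         seed = 809)
res <- run_experiment(cfg)
as.data.frame(res)
#>   fold  macro_f1 f1_class1 f1_class2 f1_class3
#> 1    1 0.3137629 0.2058824 0.5815603 0.1538462
#> 2    2 0.2637681 0.0000000 0.5739130 0.2173913
#> 3    3 0.2317901 0.0000000 0.3703704 0.3250000
attr(res, "mean_macro_f1")
#> [1] 0.2697737
```

Each row is one cross-validation fold; `macro_f1` is the unweighted mean
of the per-class F1 scores (class 1 = AFIB, 2 = SINUS, 3 = other), and
the mean row averages the folds. Three epochs of the small CNN barely
beat the majority-class baseline here — the example demonstrates the
leakage-free pipeline mechanics, not a tuned model; longer training and
the larger architectures do better (see the learning smoke tests in
`tests/testthat/test-acceptance.R`).

A thin CLI over the same functions ships in `inst/exec/ecgbench`
(`synth`, `run`, `splits`, `report` subcommands).

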
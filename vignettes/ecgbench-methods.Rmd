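---
title: "Benchmarking single-lead ECG arrhythmia classification with ecgbench"
author: "ecgbench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking single-lead ECG arrhythmia classification with ecgbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgbench)
```

## The problem

Automatic arrhythmia detection from the electrocardiogram (ECG) is usually
framed as classifying short single-lead signal segments into normal and
abnormal classes. Two families of abnormality matter in practice:
*form* abnormalities of a single heartbeat (premature ventricular or
atrial contractions — PVC, PAC) and *rhythm* abnormalities spanning many
beats (atrial fibrillation — AFIB, tachy- and bradycardias). Results in
this literature are notoriously hard to compare, for two reasons this
package addresses head on:

1. **Heterogeneous annotations.** Public datasets label their ECG in
   incompatible dialects: per-beat symbols anchored at the R-peak, rhythm
   change-point markers, or one diagnosis for a whole ~10 s recording, and
   the same arrhythmia is written differently across sources (`AFIB` vs
   `AF`). `ecgbench` unifies these through a CSV *label dictionary*
   mapping `(dataset, raw symbol, annotation kind)` to a closed vocabulary
   of unified codes, and through *task definitions* that group codes into
   ordered target classes.
2. **Evaluation leakage.** A model tested on segments from patients it was
   trained on reports wildly optimistic scores. The package's central
   evaluation scheme is *inter-patient cross-validation*: all segments of
   a patient form one indivisible group, and patients are split into k
   class-stratified folds. The patient-disjointness of every split is
   asserted programmatically (`verify_inter_patient()`) before any
   training starts.

## The pipeline

An experiment is dataset x task x transform x classifier x evaluation
scheme (`run_experiment()`):

* **Datasets** come in two categories. Beat-level datasets (long Holter
  records) are read from WFDB-style files: text `.hea` headers, 16-bit
  `.dat` signals, MIT-format `.atr` annotation streams in which rhythm
  change-points (`+` with an aux string such as `(AFIB`) are converted at
  read time to half-open episodes, the last closing at the record end.
  Recording-level datasets are signal files plus a `labels.csv` table.
  Only one lead is used; lead II is the conventional pick when a 12-lead
  source offers it.
* **Segmentation** implements four input-generation techniques: heartbeat
  windows centred on the annotated R-peak (0.72 s ~ one beat; 2.4 s
  covers the two neighbours), rhythm-episode spans, sliding windows
  (2.5 s and 10 s), and the whole ~10 s sequence. Sliding windows are
  labelled by voting: a rhythm-task window takes the class covering the
  largest portion of the span; a form-task window takes an abnormal class
  as soon as *one* in-span beat is abnormal, because abnormal beats are
  the minority worth detecting. Window predictions can be aggregated back
  to one prediction per recording by majority vote.
* **Preparation** resamples each segment to the classifier's input
  frequency (Fourier-domain band-limited resampling) and crops/zero-pads
  to a fixed length. Nothing else is done to the signal — the
  classifiers are expected to learn from raw traces.
* **Classifiers** are four 1-D neural networks plus a majority-class
  baseline (`dummy_mv`). Each network is tied to the input frequency of
  the study where it was proposed: CNN 360 Hz, ResNet 250 Hz, GRUAttNet
  500 Hz, RTA-CNN 300 Hz.
* **Evaluation** is macro F1 — the unweighted mean of per-class F1 —
  because arrhythmia classes are heavily imbalanced and micro-averaged
  scores would be dominated by the normal class. Scores are computed per
  fold and then averaged.

## Design choices where the design was open

These choices are the package's own; each is deterministic, documented,
and config-exposed where a user might reasonably want another value.

* **Windowing arithmetic.** Durations are specified in seconds, so window
  and stride lengths are `round(duration * fs)` samples; the candidate
  window count over a length-L record is `floor((L - w)/s) + 1`. Beat
  windows are floor-centred (`start = R - w %/% 2`) and boundary beats
  are dropped rather than padded — padding would fabricate signal inside
  a morphology window.
* **Tie-breaks.** A form-task window holding several distinct abnormal
  classes takes the globally rarer one (maximizing recall on minority
  classes), ties to the higher class index; an exact 50/50 rhythm
  coverage tie goes to the earlier-starting episode; aggregation ties go
  to the lowest class index; windows with no resolvable annotation are
  excluded rather than assumed normal.
* **Cropping and padding** keep the head of the signal and pad zeros at
  the tail; `fit_length()` is idempotent.
* **Stratified group k-fold.** Patients are visited in order of
  decreasing segment count (ties by id) and greedily assigned to the fold
  minimizing the mean over classes of the across-fold standard deviation
  of class counts. The greedy heuristic is deliberately simple and can
  end away from the combinatorial optimum: group-preserving placement
  cannot balance finer than whole groups, so its objective is guaranteed
  (and tested) only up to the granularity of the largest group. The
  validation fold is `(test fold + 1) mod k`, so every fold serves as
  validation exactly once; holdout splits carve a 10% patient-stratified
  validation set out of the training patients.
* **Overlap policy.** Sliding windows overlap 50% under inter-patient
  schemes; intra-patient splits use non-overlapping windows, since two
  overlapping windows sharing signal across a train/test boundary would
  leak labels.

## The neural-network engine

No deep-learning toolkit is required: the package ships a compact
reverse-mode engine in base R (`R/nn.R`) built on im2col convolutions
over BLAS matrix products and backpropagation-through-time for the GRU.
It supports exactly what the four architectures need — stride-1 'same'
1-D convolutions, width-2 max pooling, batch normalization, dropout,
leaky-ReLU (slope 0.3), sigmoid gating, bidirectional GRU, additive
attention, global average pooling and dense layers — with Adam and
early stopping. Training is single-threaded and fully seeded: shuffles
and dropout masks derive from the model seed, so runs reproduce
bit-identically.

Architecture notes, where the published descriptions left room:

* **CNN**: three conv/leaky-ReLU/max-pool blocks with (filters, kernel)
  = (5, 3), (10, 4), (20, 4), then dense 30-20-C.
* **ResNet**: stem conv + four 2-conv residual blocks (64/128/256/256
  filters, kernel 3, batch-norm and dropout between the convolutions),
  projection shortcuts around every block, max-pool after blocks 1-3,
  global average pooling, softmax head — 9 feature convolutions in
  total, projections not counted.
* **GRUAttNet**: five blocks of three 12-filter convolutions (kernels 3,
  3, 24) with dropout; we close each block with a stride-2 max-pool so
  the recurrent layer sees ~156 steps instead of 5000 — a bidirectional
  GRU over raw 500 Hz samples would dominate runtime for no modelling
  benefit. The bidirectional GRU has 12 units per direction, pooled by
  additive attention with a learned context vector.
* **RTA-CNN**: six residual temporal-attention blocks with kernels (32,
  16, 9, 9, 3, 3). The published filter list names five counts for six
  blocks; we repeat the 64 — (16, 32, 64, 64, 64, 128) — and expose the
  list as an argument. Each block combines a two-conv trunk with a
  three-conv attention branch (max-pool, convolutions, nearest-neighbour
  upsampling, sigmoid) as `trunk * (1 + attention)`, so zeroed attention
  weights reduce the block to its trunk.
* **Training defaults**: Adam, learning rate 1e-3, batch 32, at most 100
  epochs, patience 10 on validation loss, best weights restored. The
  exponential-nonlinearity loss `mean(exp(gamma (1 - p_true)) - 1)` is
  available per model spec as a harder-example-weighted alternative; the
  default loss is cross-entropy.

## The synthetic generator

`generate_beat_level_dataset()` and `generate_recording_level_dataset()`
exist so the full pipeline — file formats included — runs with no
downloads. Beats are sums of Gaussian bumps (P wave, biphasic QRS pair,
T wave) placed at cumulative RR times; PVCs are wide and inverted, PACs
narrow, attenuated and premature (the preceding RR is shortened 20%).
Rhythm classes follow their clinical heart-rate conventions: sinus
0.8 s mean RR, tachycardia 0.45 s, bradycardia 1.3 s, atrial flutter
0.55 s, supraventricular tachycardia 0.4 s, and atrial fibrillation
log-normal RR with a coefficient of variation of 0.25 — irregularity,
not morphology, is its signature. Default sampling frequency is 250 Hz,
noise is additive Gaussian (sd 0.02 mV), and per-patient class mixtures
and ectopic rates are drawn around the configured global values
(Dirichlet, concentration 10) so that patients genuinely differ —
without that, stratified patient splits would be trivial.

What the generator does *not* emulate: baseline wander, electrode noise
and artefacts, morphology drift within a patient, fusion beats, QRS
detection errors, or any realistic waveform detail beyond
class-separability. Passing tests on synthetic data therefore
demonstrate that the pipeline's bookkeeping (labelling rules, splits,
metrics, training mechanics) is correct — not that any architecture
reaches a particular score on real recordings.

## Numerical choices and degenerate inputs

* Resampling is Fourier-domain with the conventional Nyquist-bin
  split/fold; output length is `round(n * to/from)`, preserving duration
  to within one sample period. A 5 Hz test tone survives a
  250-500-250 Hz round trip within 1e-2.
* Probabilities are floored at 1e-7 before logs; softmax subtracts the
  row maximum; batch-norm uses eps 1e-5 and momentum 0.9.
* Macro F1 scores a class 0 when precision + recall is 0; a class absent
  from both truth and predictions in a fold is excluded from that fold's
  macro average (neither rewarded nor penalized) and reported.
* Degenerate requests error early and loudly: stride rounding to zero,
  input too short for the pooling stack, k exceeding the number of
  patients (with a pointer to leave-one-patient-out), unassigned or
  contradictory predefined folds, annotation indices outside the record.

## Problem sizes in the test-suite and acceptance script

The shipped checks run on one CPU in minutes: the inter-patient
guarantee uses a 40-patient, 60 s/record synthetic dataset; heuristic
quality uses 100 random instances against 1,000 random partitions each;
window-label oracle equivalence uses 1,000 random annotation streams;
the learning smoke tests train the CNN and a filter-scaled ResNet
(16/32/64/64) to macro F1 >= 0.95 on 200 separable beats per class
within 50 epochs; end-to-end determinism repeats a 10-patient,
3-fold CNN experiment. These sizes are the package's chosen trade-off
between statistical meaningfulness and a test suite that stays fast
enough to run on every change.

## Known limitations

* The engine is CPU-bound base R: fine for the benchmark sizes above,
  not for training on real multi-hour Holter corpora.
* Single-label windows only; a window containing a genuine rhythm change
  gets the majority (or abnormal-priority) label, not a label set.
* Single-lead only, by design.
* The greedy stratifier can be visibly suboptimal on tiny instances (see
  above); for datasets with many patients per fold the granularity
  effect vanishes.
* No QRS detection: beat-level transforms need annotated R-peaks.
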
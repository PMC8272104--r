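---
title: "Time-morphology ECG classification with bitecg: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-morphology ECG classification with bitecg: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitecg)
```

## The problem

Short single-lead ECG recordings from wearable devices (roughly 9 to 61
seconds, sampled at 300 Hz) must be classified into four rhythm classes:
normal sinus rhythm (`N`), atrial fibrillation (`A`), other arrhythmia
(`O`) and recordings too noisy to interpret (`P`).  Two families of
evidence matter clinically: *morphology within a beat* (is the P wave
present? is the QRS inverted or widened?) and *rhythm across beats* (are
the R-R intervals regular, wave-like, or irregularly irregular?).  The
package implements a representation and a network designed to expose both
at once, plus everything needed to train and interrogate them.

## The CS-ECM representation

The electrocardiomatrix stacks beat-anchored signal windows as matrix
rows: each detected R-peak anchors a 1.6 s segment from 0.4 s before to
1.2 s after the fiducial.  At a typical mean R-R interval of 0.8 s the
segment contains the full P-QRS-T complex *and* the following R-peak, so
reading along a row shows morphology and reading down a column shows
rhythm drift.  Segments are decimated from 480 samples (300 Hz) to 240
columns (150 Hz); 180 rows are filled.

Variable duration is handled by *size adaptation*: recordings whose
segments do not fill 180 rows are wrap-padded (row $r$ holds segment
$r \bmod n$), and recordings longer than 60 s are first cut into
`ceiling(duration / 60)` equal chunks, each yielding its own matrix.  The
result is always exactly $180 \times 240$.

Numerical choices that the construction leaves open, fixed here once:

* **Decimation.**  A 31-tap linear-phase FIR low-pass (cutoff at the new
  Nyquist) is applied per segment with edge-replicated padding, then every
  second sample is kept.  Zero-phase by symmetry, so the fiducial stays at
  column 60 (0-based).
* **Boundary beats** whose raw window crosses a signal edge are dropped,
  not zero-padded, so every row is genuine signal.
* **Amplitude scaling.**  Each chunk is robust-scaled (median subtracted,
  interquartile range divided) before segmentation, making matrices
  comparable across recordings; the scheme is configurable
  (`ecm_config(normalize = )`).
* **Extreme heart rates.**  A chunk with more than 180 usable beats keeps
  the first 180 with a warning.

## R-peak detection

The segment anchors come from a Pan-Tompkins style chain: zero-phase
Butterworth band-pass 5-15 Hz, differentiation, squaring, a centred
150 ms moving-window integral, adaptive dual-threshold peak picking with
search-back, then refinement of each detection to the extremum of largest
absolute band-passed amplitude within ±50 ms.  Refining on absolute
amplitude anchors inverted QRS complexes correctly.  The detector is
deterministic, invariant to offset and positive rescaling, and enforces a
0.2 s refractory gap.  It is also pluggable: any `rpeak_list` (e.g.
external annotations) can be passed to `build_csecms()`.

## The BIT-CNN

The network reads the matrix with three kernel shapes sharing one extent
$K = 5$: B-type $1 \times K$ filters scan along a segment (beat
morphology), I-type $K \times 1$ filters scan down a timestep column
(inter-beat consistency), T-type $K \times K$ filters capture joint
time-morphology texture.

* **Low-level blocks 1-3** (B-type only; 32/64/128 filters):
  convolution → batch-norm → ReLU → 1×1 convolution → dual pooling.
  Pooling here halves only the width (window and stride $(1,2)$), because
  B-type filters treat rows independently; repeated width pooling also
  forgives imperfect R-peak alignment across rows.
* **Super-blocks 4-6** (64/128/256 filters per path): three parallel
  paths (B, I, T), each convolution → batch-norm → ReLU → 1×1
  convolution → spatial attention → dual $(2,2)$ pooling; the paths are
  channel-concatenated in the fixed order `[B || I || T]` and dropout is
  applied.
* **Dual pooling** concatenates max- and average-pooled copies
  `[max || average]`, doubling channels, to keep both salient and
  representative local evidence.
* **1×1 convolutions** compress channels to 3/6/12/18/24/30 in blocks
  1-6.  Each width is a multiple of 3, one weight group per clinically
  meaningful region of a segment (before the first R-peak, after it, and
  around the second R-peak).
* **Feature attention**: global average and global max pooling of the
  block-6 map (180 channels) are concatenated into a 360-vector; a
  one-hidden-layer perceptron (hidden width 180) produces 360 sigmoid
  scores that gate the vector elementwise; a dense softmax head emits the
  four class probabilities.

With same-padding convolutions, spatial sizes change only at pooling:
width 240 → 120 → 60 → 30 through the low-level layer, then
$(180,30) \to (90,15) \to (45,8) \to (23,4)$ through the super-blocks
(ceiling on odd extents keeps the three paths concatenable).

### Resolving the under-determined attention hyperparameters

Two hyperparameters are not fixed by the architecture's published
description: the spatial-attention kernel and the channel-attention
hidden width.  The package resolves them against the parameter audit.
An exhaustive enumeration of structurally plausible variants shows
exactly one configuration that keeps conventional biases on every
convolution and dense layer and reproduces the published totals of
2,015,043 parameters (2,011,907 trainable):

* spatial attention as a bias-free $3 \times 3$ convolution over the
  2-channel (channel-mean, channel-max) stack, with the weights *shared
  across the three paths of a super-block* (one attention module per
  super-block, applied three times);
* channel-attention perceptron $360 \to 180 \to 360$ with biases
  (hidden width 180, i.e. reduction ratio 2).

Under that reading the non-trainable remainder is exactly the
$2 \times 1568$ batch-norm running statistics.  `count_parameters()`
reports the audit;

```{r audit}
count_parameters(bitcnn(bitcnn_config(), seed = 1))
```

### Other fixed conventions

Batch-norm follows each shaped convolution (never the 1×1), with
$\varepsilon = 10^{-3}$ and running-statistic momentum 0.9 (the smaller
momentum lets evaluation-mode statistics converge within short training
runs).  Dropout defaults to 0.3.  Dual-pool concatenation order is
`[max || average]`; tie-breaks in every max operation take the first
maximum in column-major scan order.  The class order is `N, A, O, P`
everywhere, including argmax tie-breaking in `aggregate_record_prediction()`.

### Implementation

No R deep-learning framework is involved: forward passes,
back-propagation through every module (including both attention
mechanisms), the Adam optimizer and Grad-CAM are implemented in compiled
C++ (im2col + GEMM convolutions).  The backward pass is verified against
central finite differences in the test suite; where max operations make
the loss non-differentiable at exact ties, the implementation takes the
standard first-argmax subgradient.

## Training protocol

`train_bitcnn()` minimizes categorical cross-entropy with Adam (learning
rate 0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-7}$)
in mini-batches of 16, up to 100 epochs with early stopping after 20
epochs without validation-loss improvement and restoration of the
best-validation weights.  Which quantity "improvement" refers to is not
pinned down by the protocol's description; validation loss is used here.
Shuffling and dropout are seeded, so runs are reproducible to floating-point
accumulation order.

Evaluation uses stratified five-fold cross-validation: per fold, 20% of
record ids are the test set and the remaining 80% is split 90/10 into
training and validation.  Splitting is by record id so chunks of one
recording never straddle sets.  For the class-imbalanced source dataset,
the training pool is rebalanced to 4000/2500/3000/1000 records
(N/A/O/P) by undersampling without replacement and oversampling by whole-
copy duplication plus a seeded top-up; resampling is applied to the 80%
pool *before* the 90/10 split, which is the only ordering consistent with
undersampling normal to 4000 out of a ~4061-record pool.  Oversampling
duplicates records verbatim — no augmentation is invented.

## Interpretability

`grad_cam()` implements gradient-weighted class activation maps: the
gradient of the *pre-softmax* class score (the standard choice; it makes
the map invariant to shifting all logits) with respect to a block's
output is averaged over space per channel; the weighted channel sum is
rectified and bilinearly upsampled to the input grid.  For super-blocks,
`grad_cam_by_filter_type()` restricts the sum to the channel range of one
path, which is well-defined because the concatenation order is fixed; the
pre-ReLU maps of the three paths sum exactly to the full pre-ReLU map.
For low-level blocks the "block output" is the post-concatenation map;
for super-blocks, the post-dropout position (dropout being inactive at
evaluation).  `embed_2d()` reduces feature vectors with PCA (at most 50
components) and embeds them in 2D with t-SNE (perplexity 30 by default,
reduced for small n), both seeded.

## The synthetic data generator

`generate_recording()` builds each beat as a sum of Gaussian bumps (P, Q,
R, S, T) placed at rhythm-driven fiducials, 300 Hz, with durations drawn
from a truncated normal (mean 30 s, sd 10 s, range 9-61 s) to mimic the
duration profile of short wearable recordings.  Class models:

* `N`: mean R-R 0.8 s with slow sinusoidal heart-rate variability
  (amplitude 0.05 s at 0.1 Hz) and small per-beat jitter; P amplitude
  0.15, T amplitude 0.3 (R normalized to 1).
* `A`: P amplitude exactly zero; R-R drawn per beat from a Gamma
  distribution with mean 0.7 s and coefficient of variation 0.25
  (irregularly irregular, faster than normal); a low-amplitude 4-9 Hz
  fibrillatory baseline oscillation.
* `O`: the normal backbone with per-beat ectopic probability 0.15; an
  ectopic beat is premature (0.6× the base interval), has a widened,
  inverted QRS without a P wave, and is followed by a 1.4× compensatory
  pause.
* `P`: beats remain placed (so ground truth stays meaningful) under
  broadband white noise at −3 dB signal-to-noise.

All classes share a 0.25 Hz baseline wander and mild white noise.  Every
random draw flows from one master seed through a documented per-record
derivation, so datasets are bit-reproducible.  The generator emulates
rhythm statistics, class-defining morphology and noise levels; it does
*not* emulate electrode pop artifacts, the heterogeneity of real "other"
arrhythmias, inter-patient morphology variation, or mixed rhythms within
one recording.  Passing tests on this data therefore demonstrates that
the pipeline learns and separates the *defining* class features, not that
it attains any particular accuracy on real clinical recordings.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise a scaled-down network
(`bitcnn_config_small()`: filters 8/16/32 and 16/32/64 per path, 1×1
widths 3/3/6/6/6/6, ~160k parameters) trained for up to 5 epochs on 200
synthetic recordings per class, sizes chosen so a full run completes in
minutes on one CPU core while leaving the architecture's topology — all
six blocks, three filter shapes, both attention mechanisms — intact.  The
full-size configuration is exercised forward-only (parameter audit, shape
measurements, prediction contracts).  On the synthetic task the scaled
network reliably exceeds 80% held-out macro F1, far above the 25%
four-class chance floor; the published cross-validated scores on the real
challenge data are *not* reproduced here, as that would require the
external dataset and GPU-scale training.

## Known limitations

* The MAT reader supports exactly the single-variable numeric-vector
  dialect of the challenge files (including zlib-compressed elements),
  not general MAT containers.
* Training determinism is best-effort: results are reproducible on a
  given BLAS but may differ in the last bits across BLAS builds.
* The detector is tuned for 300 Hz adult single-lead ECG; other sampling
  rates work through `ecm_config(source_fs = )` but the band edges are
  fixed.
* Oversampling duplicates matrices exactly; with very small classes this
  can overfit — the resampling plan is meant for the source dataset's
  scale.
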
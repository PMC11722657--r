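---
title: "Scoring and predicting driving-related cognitive ability"
author: "drivecog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and predicting driving-related cognitive ability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivecog)
```

## Overview

`drivecog` implements a two-stage framework for driving-related cognitive
ability. The first stage turns a driver's task performance during a scripted
simulator session into a four-level ability grade: ten indicators spanning
cognitive decision-making, vehicle control and psychological regulation are
encoded, z-standardized, oriented so larger always means better, aggregated
into three dimension scores, combined into a weighted composite, and binned
at Gaussian-rule quartile thresholds. The second stage predicts that grade
directly from the multimodal sensor record of the drive — 4 physiological
channels (electrodermal activity, heart rate, respiration rate, perinasal
perspiration) and 11 non-physiological channels (gaze, pupil diameter,
vehicle telemetry, facial emotion) — using a dual-branch Transformer encoder
whose two class-token features are fused by an attentional feature fusion
(AFF) gate.

Because the underlying 68-participant simulator dataset is external, the
package ships a synthetic cohort generator that plants a latent per-driver
ability in both the task indicators and the sensor statistics, so every
stage of the pipeline is exercisable and testable end to end.

## The ability score

Each driver contributes ten indicators. Three belong to the
decision-making dimension (secondary-task avoidance count, secondary-task
accuracy, signal anticipation), four to vehicle control (emergency reaction
time, collision extent, secondary-task reaction time, line crossing) and
three to psychological regulation (NASA workload, anxiety, Type A/B
personality score).

Counterbalance group A performed an extra task during the emergency
scenario, so its reaction times carry an additive bias. The default
compensation subtracts the difference of group means,
$\mathrm{CRT} = \overline{RT}_A - \overline{RT}_B$, from every group-A
reaction time. A literal variant, $(\sum RT_A - \sum RT_B)/N$, is kept
behind `mode = "literal_eq2"`; the two coincide only for equal group sizes
of $N/2$. The mean-difference reading is the default because it is the
unambiguous statement of intent ("the difference between the average
reaction times"), and it is idempotent: a second application finds a
compensation of zero.

Indicators are standardized column-wise with the sample standard deviation
(divisor $n-1$; a constant column becomes all-zero with a warning) and
multiplied by an orientation sign so that larger always means better. The
shipped orientation negates both reaction times, collision extent, line
crossing, NASA workload and anxiety; it is a configurable argument because
aggregation is meaningless without a declared orientation.

Dimension scores are the means of a dimension's oriented z-columns — this
keeps all three dimensions on the z scale so that a single weight vector is
comparable across them. The composite is
$\mathrm{Score} = \sum_{i=1}^{3} W_i \cdot \mathrm{dim}_i$ with shipped
default weights $W = (0.3898, 0.3182, 0.2920)$ for decision-making,
control and psychological regulation.

### PCA-derived weights

`fit_pca_weights()` re-derives the weights from data: PCA on the oriented
z-matrix (whose covariance is the component correlation matrix), loading
signs fixed so each principal component's largest-magnitude loading is
positive, and a per-variable importance
$w_i = \sum_{k \le K} |L_{ik}| \, V_k$ with $V_k$ the variance ratio of
component $k$. We take the loading *magnitudes* before the variance-weighted
sum: a signed sum lets a variable's contributions cancel across components,
which makes the weights depend on the arbitrary rotation of near-degenerate
eigenvectors — on isotropic data the signed construction produces dimension
weights that wander by up to ±0.3, whereas the magnitude reading
concentrates at the symmetric value 1/3 (±0.03 with all components
retained). $K$ defaults to the smallest number of components reaching 80%
cumulative variance; on exactly isotropic data every eigenvalue is equal
and truncation is arbitrary, so symmetry checks should retain all
components. Dimension weights are the means of $w_i$ over each dimension's
variables, normalized to sum 1.

### Grading

Thresholds follow the Gaussian rule $Q_i = \mu + \sigma z_{p_i}$ at
$p = (0.25, 0.5, 0.75)$, so $Q_2$ is always the cohort mean. Grades are
assigned on left-closed intervals — $[\min, Q_1)$ "Insufficient",
$[Q_1, Q_2)$ "Fair", $[Q_2, Q_3)$ "Good", $[Q_3, \max]$ "Excellent" — with
a score exactly on a threshold going to the higher class. A cited
transformation said to bring scores "closer to a normal distribution" has
no operational definition we could implement, so no transform is applied by
default; `rank_inverse_normal()` is provided for cohorts whose composite is
visibly non-Gaussian.

## Signal preparation

Recordings are trimmed (the asynchronous start-up seconds removed),
interior gaps linearly interpolated with nearest-value fill at the edges,
min-max normalized to [0, 1] per channel, resampled onto a common grid, and
cut into overlapping windows (`floor((T - L)/S) + 1` windows of length
`L` stepped by `S`; defaults 60 s / 5 s).

Two normalization scopes are supported. The default, per-recording, mirrors
normalizing each session before windowing. The alternative,
per-training-set (`fit_normalization()`), computes the channel extrema on
training subjects only and reuses them verbatim on held-out subjects; this
is the honest choice when evaluation must be free of leakage, at the cost
of occasional clipping when a test subject exceeds the training range.

The common grid rate is 1 Hz, making a 60 s window a 15×60 image. This is
the only rate at which all three patch geometries used by the models tile
their images evenly: 4×4 patches tile the 4×60 physiological image into 15
patches, 11×4 patches tile the 11×60 non-physiological image into 15, and
15×15 patches tile the full 15×60 baseline image into 4. Faster channels
are bin-averaged onto the grid (the mean is conserved for integer rate
ratios); slower ones are linearly interpolated. Windows are half-open
`[start, start + L)`, 0-indexed from the post-trim recording start, and
every window inherits its driver's single ability grade.

## The prediction model

Each branch is a small ViT-style encoder: patches are flattened and
linearly projected to `embed_dim` tokens, a learned class token is
prepended, and a fixed sinusoidal positional encoding is added (class token
at position 0). Each of `n_layers` pre-norm blocks applies multi-head
self-attention and a two-layer feed-forward network (hidden width
`ffn_ratio * embed_dim`, GELU), each sublayer wrapped in layer
normalization, a residual connection, and dropout (rate 0.2). The branch
output is the final-layer class-token row; no final layer norm is applied,
so a zero-depth branch is the identity on the class token.

The three variants mirror the ablation design:

* **baseline** — one encoder on the whole 15-row image with 15×15 patches;
* **dual_branch** — separate physiological (4×4 patches) and
  non-physiological (11×4 patches) encoders, class-token features
  concatenated before the linear head;
* **dual_branch_aff** — the two features fused by the AFF gate.

The AFF gate operates on the two class-token vectors, so its "point-wise
convolutions" reduce to dense channel bottlenecks ($D \to D/r \to D$,
ReLU, default $r = 4$). With $u = x_p + x_{np}$, the mask is
$m = \sigma(\mathrm{local}(u) + \mathrm{global}(\bar u))$ where the global
path sees the channel-mean broadcast of $u$, and the output is the strict
convex combination $z = m \odot x_p + (1 - m) \odot x_{np}$. Every mask
entry lies in (0, 1), so each fused component lies between its two inputs
and equal inputs are fixed points. The multiplicative stream of the
original construction enters through the mask application $m \odot x$.

All forward and backward passes are hand-derived reverse-mode gradients
over base-R BLAS matrix operations — a deliberately self-contained
implementation whose correctness is pinned by a finite-difference gradient
check in the test suite (every parameter tensor, relative tolerance 1e-3).
Initialisation is fan-in scaled Gaussian ($\mathrm{sd} = 1/\sqrt{d_{in}}$)
for projections; the classification head starts near zero (sd 0.01) so the
initial loss is $\approx \ln 4$ on balanced four-class data.

Training minimises cross-entropy with Adam (betas 0.9/0.999), initial
learning rate 6e-4, and step decay (default: halving every epoch, the
published schedule for a 100-epoch run; batch 128). Plain cross-entropy is
used despite class imbalance, matching the framework being reproduced. One
integer seeds initialisation, shuffling and dropout, so runs are
reproducible per machine.

## Evaluation

`loso_folds()` builds leave-one-subject-out folds; `evaluate_model()`
trains per fold and pools all test predictions before computing metrics
once (per-fold reports are retained). Accuracy is correct/total — the only
consistent multiclass reading of the binary TP/TN form — and F1 is computed
per class one-vs-rest and macro-averaged (robust to the imbalance the
four-grade labels typically show); micro-F1, which equals accuracy here, is
also reported. Confusion matrices are reported raw and row-normalized by
true class. `run_ablation()` runs any set of variants over identical folds
and seeds and reports per-cell and summary accuracy/F1.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` draws a per-driver latent ability vector (decision,
control, psych) from a trivariate Gaussian with pairwise correlation 0.3;
the overall latent ability applies the shipped dimension weights to it,
which makes label recovery by the scoring pipeline an identifiable target.
Indicators follow linear-Gaussian links for continuous measures and
thresholded-Gaussian links for binary/ordinal ones, with a configurable
noise scale; discretization thresholds are placed relative to the total
predictor scale so class balance does not depend on the effect size.
Group A receives a configurable additive emergency reaction-time offset
(default 0.3 s) emulating its extra task; how large that bias was in the
original experiment is not recoverable, so it is a free parameter.

Channels are AR(1) processes (coefficient 0.9) at their native rates
around an ability-shifted baseline, with raised-cosine bumps at scripted
events (secondary tasks, intersections, one emergency). The ability enters
twice: as a mean shift (lower psychological ability raises the EDA
baseline) and as a noise-scale factor (lower control ability raises
lane-offset variance). The noise-scale route matters because per-recording
min-max normalization removes absolute levels; what survives into the
windows is each channel's roughness relative to its event bumps, which is
monotone in ability.

The thresholded links place a ceiling on label recovery: a balanced binary
indicator retains a correlation of only $\sqrt{2/\pi} \approx 0.80$ with
its latent, capping the score–latent correlation near 0.986 and quartile
agreement near 0.87 even at effect size 3 and noise 0.1. Passing the
recovery checks therefore demonstrates that the pipeline loses little
beyond this structural limit, not that real cohorts would grade this
cleanly. More generally the simulator makes no claim to physiological
realism — no heart-rate variability structure, no EDA decomposition, no
vehicle dynamics — so model accuracies on it say that the architecture can
extract a planted multimodal signal, not that it would reach any particular
accuracy on real drivers.

`simulate_fusion_windows()` is a separate, sharper probe for the ablation:
each subject carries one latent factor per modality, windows encode them as
level shifts, and the label is their joint sign pattern — a balanced
quadrant design in which neither modality alone identifies the class. It
orders architectures by how well they combine modalities.

## Problem sizes and numerical choices

The desk-scale experiments used throughout the vignette, tests and
acceptance script run a reduced geometry chosen to keep a full pipeline
run on one CPU core in minutes: embedding dimension 32, 2 layers, 2 heads,
batch 32, cohorts of 40 drivers with 300 s sessions (≈ 1,960 windows), and
15 training epochs. At 15 epochs the published halving schedule freezes
training prematurely, so the scaled experiments decay by 0.9 per epoch
instead; the published defaults remain `train_config()`'s defaults. The
grade-recovery experiment also raises dropout from 0.2 to 0.5 and holds out
a class-stratified 20% of drivers (two per grade): with only 32 training
subjects and windows that overlap by 55 of 60 seconds, the effective sample
is the subject count, and heavier dropout is what keeps the encoder from
memorising subject-specific noise realisations; stratification keeps all
four grades present in the 8-driver test set. Other numerical choices:
layer-norm epsilon 1e-5; softmax rows are max-stabilised; the σ = 0 guard
maps constant channels and components to zero rather than NaN; ties at
grade thresholds go to the higher class; `floor`-based window counts drop
any partial final window.

## Known limitations

* The encoder processes pooled class-token vectors through the fusion
  gate; fusing full token maps is a plausible alternative the original
  description leaves open.
* Training is single-threaded R; the paper-scale geometry (128/12/8,
  31k windows, 100 epochs) is out of desk-scale reach, and published
  headline accuracies on the external dataset are not reproduction
  targets here.
* The per-recording normalization default mirrors the reproduced
  preprocessing but mildly leaks recording-level statistics into windows;
  use `fit_normalization()` for leakage-free protocols.
* `read_cohort()`/`write_cohort()` round-trip to CSV at ~1e-9 relative
  precision, not bit-exactly.
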
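---
title: "Spatio-temporal graph convolutional classification of parcellated brain time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal graph convolutional classification of parcellated brain time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stgcnet)
```

## The problem

Resting-state fMRI yields, after preprocessing and parcellation, one
multivariate time series per subject: `T` timepoints by `N` atlas regions of
average BOLD signal (the package ships the 90-region AAL labelling as its
reference parcellation). Group differences between patients and controls in
such data are carried less by mean signal than by functional connectivity —
the correlation structure between regions — and by its dynamics over time.
`stgcnet` implements a spatio-temporal graph convolutional network (ST-GCN)
classifier for this setting, together with the surrounding protocol: sliding
window segmentation with subject-level majority voting, stratified
cross-validation, a weight-tracing interpretability module that scores
regions by their contribution to the classifier, an occlusion baseline for
comparison, and a weighted graph metric/symptom association analysis with
FDR control.

## The spatio-temporal graph

Each subject's series is treated as a graph whose nodes are (region, time)
pairs. Spatially the graph is shared by all subjects: subjects' series are
concatenated along time (in canonical subject-id order, making the result
independent of manifest ordering), region-by-region Pearson correlations are
computed on the long series, Fisher z transformed, and the absolute value is
taken with the diagonal zeroed. Two choices deserve comment:

* **Sign handling.** Fisher-z connectivity can be negative, but the spectral
  machinery below needs nonnegative edge weights for a well-behaved
  normalized Laplacian. The default takes `|z|`; a positive-part variant
  (`negative = "clip"`) is available. Signed weights are retained where they
  are meaningful — in the per-subject graphs of the association module.
* **Input features.** Segments enter the pipeline as raw windowed BOLD
  arrays of shape (batch, 1 channel, window, N). What the network consumes
  is a configuration choice (`model_config(input = )`). The default,
  `"fc"`, expands each segment into its dynamic-connectivity sequence:
  sliding sub-windows of `fc_subwindow` TRs (default half the window,
  stride 1) each contribute a Fisher-z FC frame, and a node's input
  channels are its connectivity profile — the row of that frame. The
  alternative, `"bold"`, feeds the z-scored raw segment with a single
  channel, the node-feature reading in which node features are the blood
  oxygen signals themselves. Both are implemented and tested; the
  connectivity representation is the default because group differences in
  this problem live in second-order structure, which the `"bold"` path can
  reach only indirectly through nonlinearities — in our desk-scale
  experiments the `"fc"` representation trains to criterion in minutes
  where the raw-signal representation plateaus far below it. One
  consequence worth noting: with connectivity-profile channels, region
  relabelling permutes input channels as well as nodes, so the exact
  node-permutation invariance of voted predictions holds in `"bold"` mode
  (where it is asserted in the tests) and only up to channel re-indexing
  in `"fc"` mode.

## The network

Three ST-GC blocks with channel sizes `(c1, c2, c3)` are stacked, followed
by global average pooling over the time and node axes and a linear layer
onto two class scores. Each block runs two parallel pathways whose outputs
are summed elementwise and passed through a final temporal module:

* **MSGCN** — multi-scale spectral graph convolution. The shared adjacency
  `W` gives the symmetrically normalized Laplacian
  `L = I - D^{-1/2} W D^{-1/2}`, rescaled by its exact largest eigenvalue
  (`N` is small, so the eigendecomposition is cheap and the usual
  `lambda_max = 2` shortcut is unnecessary). Chebyshev polynomials
  `T_0 = I, T_1 = Lt, T_k = 2 Lt T_{k-1} - T_{k-2}` of the rescaled
  Laplacian form the multi-scale filter bank; order `k` reaches `k`-hop
  neighbourhoods. The `K_s` per-scale responses are concatenated along
  channels and mapped to the output width by a learned per-position linear
  map ("MLP"), then normalized and passed through a ReLU. The reference
  configuration uses `K_s = 8`.
* **MSTCN** — multi-scale dilated temporal convolution. `K_T` parallel
  branches each reduce channels by `1/K_T`, then convolve along time with
  an odd kernel (default width 3) at branch-specific dilation (defaults
  `1..K_T`; reference `K_T = 4`). Symmetric zero padding of
  `dilation * (kernel - 1) / 2` preserves the window length. Branch outputs
  are concatenated and a residual path (identity when the channel counts
  match, a learned 1x1 map otherwise) is added before normalization and the
  nonlinearity.
* **MSG3D** — fused spatio-temporal convolution. The input is unfolded into
  overlapping windows of `tau = 3` consecutive frames; the tiled
  `3N x 3N` adjacency with every block equal to `W + I` (self-loops let a
  node attend to itself across frames) defines a fused graph over which the
  same multi-scale Chebyshev convolution runs; a learned per-channel
  three-tap combination collapses the frame axis back.

Design choices the architecture description leaves open were resolved as
follows: scale outputs are concatenated (not summed) before the learned
map, so per-scale information stays separable; the two pathways are fused
by an elementwise sum, which is parameter-free and shape-safe; no temporal
down-sampling is applied between blocks, so every forward operation
preserves `(T, N)` and only channels change. The whole network is
permutation-equivariant in the node labelling up to the final pooling —
relabelling regions (together with `W`) permutes every intermediate tensor
identically and leaves voted predictions unchanged; this is asserted in the
test suite.

## Training protocol

Training minimizes segment-level cross-entropy with Adam (defaults: learning
rate 1e-3, batch size 16, at most 100 epochs, patience 10, decoupled weight
decay 1e-4). Subject-level decisions are made by majority voting over a
subject's window segments, with ties broken towards the class favoured by
the mean patient-class probability. Each cross-validation evaluation holds
out one fold for testing and the next fold for validation (60/20/20 at
`k = 5`); the epoch with the best validation voted accuracy is
checkpointed, and training stops after `patience` consecutive
non-improving epochs.

Three details of the loop matter in the small-sample regime this package
targets and are worth stating explicitly:

* **Window resampling.** Training segments are re-drawn (new random window
  starts) every epoch. With a fixed segment set the network memorizes the
  segments; resampling turns the sliding window into data augmentation and
  forces features that generalize across window positions.
* **Class-balanced minibatches with precise normalization statistics.**
  Batch normalization on small batches lets a network key on minibatch
  composition. Minibatches therefore interleave shuffled patient and
  control segments (composition is constant, so it carries no label
  information), and after each epoch the running statistics are
  re-estimated under the current parameters over several training batches,
  so evaluation-time normalization matches what training produced. A
  `bn_mode = "running"` variant that normalizes with EMA statistics during
  training is available but not the default: with the statistics treated as
  constants in the gradient, activations can outgrow the lagging EMA, which
  in our experiments destabilized training.
* **Per-segment standardization.** Each window is z-scored per region
  before entering the model. Amplitude is uninformative in this design —
  group differences are planted in (and, in the motivating data, expected
  in) the correlation structure — and standardization removes a nuisance
  dimension.

## Interpretability

The weight-tracing module scores regions by walking the classifier
backwards from its decision: the channels of the pre-pool feature tensor
with the largest absolute final-layer weights are selected (`top_n`
defaults to `c3 / 4`); within each selected (segment, channel) slice the
`ceiling(mark_fraction * window * N)` elements contributing most to the
pooled average are marked (largest signed values by default, since the mean
over a fixed count is maximized by the largest entries; absolute-value
marking is a switch); and each region's importance score counts the marks
in its node column, summed over segments, channels and time, then
aggregated across folds (sum by default, mean as an option). Ties at the
marking cut are resolved towards the earliest (time, region) position and
flagged in the report. Two conservation properties pin the arithmetic down:
scores over regions always sum to the number of marked elements, and
increasing `mark_fraction` never decreases any region's score.

The selection step works on the channel axis of the `(B, c3, window, N)`
pre-pool tensor, yielding `(B, top_n, window, N)`; descriptions of this
procedure sometimes print the shape with the last axis named by the channel
count, which is inconsistent with selecting channels and is treated here as
a typo.

The occlusion (perturbation) baseline is a reconstruction of the standard
procedure, and is labelled as such: for each region, its input signal is
replaced — zeroed or time-permuted within each segment (the default, which
preserves the marginal distribution while destroying cross-correlations) —
and the importance is the drop in mean correct-class probability on the
identical held-out subjects. `rank_overlap()` compares the two rankings at
any depth.

## Graph metrics and association analysis

Each patient's signed Fisher-z connectivity matrix defines a weighted
graph. Three node metrics are computed under the `|w|` convention (a
positive-only switch exists, and the convention is recorded in the output):
strength (weighted degree), closeness centrality with edge lengths
`1 / |w|` (unreachable nodes give closeness 0), and the Onnela
geometric-mean weighted clustering coefficient with weights normalized by
the graph maximum (degree < 2 nodes score 0; the named coefficient admits
several weighted forms, and the geometric-mean variant was chosen as the
field's most common). Associations with symptom scores are tested one
(region, metric) pair at a time in the linear model
`score ~ metric + sex + age + education` on patients, with
Benjamini–Hochberg FDR applied within each metric family across regions
(the family definition is recorded in the output; applying it per metric is
the conservative reading of testing "one node attribute" at a time).
Demographic comparisons use the uncorrected Pearson chi-square for sex and
the pooled two-sample t (computable directly from printed mean/SD/n
summaries) for age and education.

## The synthetic cohort generator

No clinical data ship with the package, so validation rests on a generator
whose ground truth is known. Subjects are Gaussian vector-autoregressive
(order 1) series: `x_t = phi x_{t-1} + e_t` with innovation covariance
`(1 - phi^2) Sigma`, so the stationary cross-covariance is exactly `Sigma`;
`phi = 0.5` approximates BOLD autocorrelation at TR = 2 s. The control
covariance has unit diagonal, a fully connected planted block (5 regions,
entries around 0.3) and sparse random entries elsewhere (density 0.1,
magnitudes 0.15–0.4, random signs), floored to positive-definite by
eigenvalue clipping. The patient covariance scales every off-diagonal entry
touching the planted set by `1 + delta` (`delta = 1` by default; the
difference is confined to those rows and columns before the projection).
The group difference is planted in covariance rather than mean because
every stage of the pipeline — connectivity, adjacency, graph metrics — is
covariance-driven; a mean shift would be erased by per-window
standardization and would validate nothing.

Patient symptom scores are generated from each subject's *realized*
connectivity: `150 + 600 * (mean within-set |Fisher z|) + 0.5 (age - 32) +
5 male - (education - 13.5) + N(0, 15)`, with covariates drawn
independently of group (age ~ N(32, 9) truncated to 18–50, two-thirds male,
education ~ N(13.5, 2.9) truncated to 9–22, mirroring the demographic table
of the cohort the generator emulates; the score scale sits in the central
range of the IBS symptom-severity instrument that motivates the field's
score, and the coefficient and noise give a signal-to-noise ratio at which
an n = 40 association analysis has realistic, not saturating, power).

What the generator does *not* emulate matters for interpreting green tests:
physiological noise and scanner drift, spatial autocorrelation of the
parcellation, site or motion confounds, heterogeneous effect sizes across
subjects, and any nonstationarity of connectivity within a scan. Passing
the recovery benchmarks shows the pipeline's machinery is correct and
sensitive at the stated effect size — not that comparable accuracy is
attainable on clinical data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale: 40 + 40
subjects, 30 regions, 120 timepoints, window 40 TRs, channels (8, 16, 32),
`K_s = 4`, `K_T = 2`, chosen so the full benchmark suite completes in
minutes on one CPU while exercising every code path; the full-size preset
(79 + 79, 90 regions, 170 timepoints, window 140, `K_s = 8`, `K_T = 4`,
channels (16, 32, 64)) is a constructor flag away. Within the desk
benchmark, the main cross-validation uses five folds with up to 10 epochs;
the label-permuted null uses a two-epoch schedule (a null model is at
chance regardless of training length); the region-subset comparison
(planted set versus ten random size-matched sets) uses three folds and
four epochs under one common schedule for every subset, so the comparison
is fair; and the occlusion analysis perturbs the held-out test set of the
first fold with eight voting segments per subject. Further numerical
conventions: correlations at `|r| = 1` are clipped to `1 - 1e-7` before the
Fisher transform (keeps `atanh` finite, preserves ranking) with a warning;
`lambda_max` is computed exactly; eigenvalue flooring uses `1e-4`; the
backward pass is hand-derived and verified against central finite
differences through the entire network in the test suite; forward passes at
inference time are chunked (32 segments) to bound memory. All randomness —
folds, initialization, window draws, shuffling, dropout, permutation
occlusion — flows from integer seeds through a single splitting function,
making every result reproducible bit-for-bit from (config, seed).

## Known limitations

The training loop is single-threaded CPU code; paper-scale sweeps (14
window sizes at 90 regions) are feasible but slow. The classifier's
accuracy on the synthetic benchmark depends on the planted effect size; at
`delta` well below 1 the desk-scale schedule will not separate the groups.
The occlusion module reconstructs a procedure whose original internals are
not fully specified, so its rankings should be read as a baseline for
comparison rather than a reimplementation. And node-permutation
equivariance means the network cannot use region identity per se — all
spatial specificity enters through the shared adjacency, so a poorly
estimated adjacency bounds what the spatial convolutions can express.
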
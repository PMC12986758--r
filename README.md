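# stgcnet

Spatio-temporal graph convolutional networks for classifying parcellated
brain fMRI time series, with a weight-tracing region-importance module and
graph-metric association analysis.

## The problem

Resting-state fMRI, after preprocessing and atlas parcellation, gives one
T × N matrix per subject: T timepoints of average BOLD signal in each of N
brain regions (the package ships the 90-region AAL labelling). Telling a
patient group from controls in such data is a question about functional
connectivity — the correlation structure between regions — and its dynamics,
not about mean signal. `stgcnet` implements, end to end:

* **The classifier.** A spatio-temporal graph convolutional network
  (ST-GCN): three ST-GC blocks, each combining multi-scale Chebyshev
  spectral graph convolution over a shared connectivity-derived adjacency
  (`K_s` scales of `T_k(L̃)`, `L = I − D^{−1/2} W D^{−1/2}`), multi-scale
  dilated temporal convolution, and a fused 3N-node spatio-temporal pathway
  over a tiled `W + I` adjacency spanning three consecutive frames; then
  global average pooling and a linear classifier. Subjects are classified
  by majority voting over sliding-window segments (stride 1, random
  starts), inside a stratified 60/20/20 five-fold cross-validation.
* **Interpretability.** A weight-tracing module that selects the pre-pool
  feature channels with the largest final-layer weights, marks the elements
  of each (window × region) slice that contribute most to the pooled
  average, and counts marks per region — plus an occlusion baseline
  (zero or time-permute one region's input, measure the drop in correct-class
  probability) and top-k rank-overlap comparison.
* **Network statistics.** Per-subject weighted brain graphs from Fisher-z
  connectivity; strength, closeness and (Onnela) clustering per region;
  covariate-adjusted linear-model association with symptom scores under
  Benjamini–Hochberg FDR; demographic group tests (pooled t from summary
  statistics, uncorrected chi-square).
* **A synthetic cohort generator.** Gaussian VAR(1) subjects with a planted
  connectivity effect (patient covariance inflated on a known region set)
  and symptom scores driven by each subject's realized planted
  connectivity — the ground truth against which the whole pipeline is
  validated.

The neural network (forward and hand-derived backward passes, batch
normalization, Adam) is implemented in R with compiled kernels for the
memory-bound steps; no deep-learning framework is required.

## Worked example

```r
library(stgcnet)

# a desk-scale synthetic cohort: 40 + 40 subjects, 30 regions, 120 TRs,
# 5 planted regions whose connectivity is doubled in patients
sim <- simulate_cohort(synth_config(seed = 1))
cohort <- sim$cohort
sim$ground_truth$planted_labels
#> [1] "R001" "R002" "R003" "R004" "R005"

# five-fold cross-validated training (about 8 minutes on one CPU)
cv <- cross_validate(cohort, desk_train_config(seed = 1),
                     desk_model_config(seed = 1), k = 5, seed = 1)
glance(cv)
#> # A tibble: 1 × 6
#>   n_folds mean_accuracy sd_accuracy mean_auc window_size n_subjects
#>     <int>         <dbl>       <dbl>    <dbl>       <int>      <int>
#> 1       5           0.9      0.0559    0.988          40         80

# which regions drive the decisions?
imp <- region_importance(cv, cohort)
head(imp, 5)          # the five planted regions fill the top five ranks
#> # A tibble: 5 × 3
#>   region score  rank
#>   <chr>  <dbl> <int>
#> 1 R005   23501     1
#> 2 R003   18931     2
#> 3 R002   17627     3
#> 4 R001   16408     4
#> 5 R004   13354     5
autoplot(imp)         # ranked bar chart

# graph-metric association with the generated symptom scores (patients)
metrics <- node_metric_table(cohort[cohort$group == "patient", ])
assoc <- glm_association(metrics, cohort[, setdiff(names(cohort), "series")])
dplyr::filter(assoc, q_value < 0.05, metric == "degree")
```

On this cohort the voted cross-validated accuracy is 0.90 (label-permuted
null: 0.51), the interpretability ranking places all five planted regions
at the top,
and the planted-region strength metric associates with the synthetic
symptom scores at q < 0.05 for four of the five planted regions with no
false positives.

`model_config()` exposes the full-size architecture (channels 16/32/64,
`K_s = 8`, `K_T = 4`); `synth_config(paper_scale = TRUE)` generates a
79 + 79 subject, 90-region, 170-timepoint cohort; `window_sweep()` repeats
the cross-validation over a grid of window sizes.

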
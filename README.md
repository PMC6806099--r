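# uosdfs — unsupervised online feature selection for multispectral quality classification

Classifies multispectral-imaging samples of a food product into two
microbiological quality classes — fresh (total viable counts ≤ 2 log CFU/g,
releasable) versus spoiled (TVC ≥ 6 log CFU/g) — from 36 spectral features:
the mean and standard deviation of normalized reflectance in 18 bands
(405–970 nm). Because test samples come from different batches, shelf-life
stages and instrument states than the training set, a feature that is
informative for one sample may be drifted or corrupted for the next. The
package therefore selects a fresh feature subset **per test sample** with a
three-stage dynamic feature selection (DFS) cascade before classifying:

1. **Fisher score elimination** (training-dependent):
   `FDS_k = SB_k / SW_k`, the between-class scatter of the class means over
   the summed within-class variances; features below `th_fd` (on the
   max-normalized score) are dropped.
2. **Mahalanobis ratio** (online, per sample): with squared distances
   `M_d = (s_k − b̄_dk)² / σ²_dk` to each class, features with
   `MR_k = min(M₁,M₂)/max(M₁,M₂) > th_mr` are dropped — the sample is either
   ambiguous between classes or far from both on that feature.
3. **Class-fit probability** (online): `P_k = max_d N(s_k; b̄_dk, σ_dk)`;
   features with `P_k < th_p` are dropped as gross outlier values.

The surviving features train a linear-kernel SVM (LDA/QDA pluggable) for that
one sample. The three thresholds are tuned by exhaustive grid search on a
validation split (default 5 × 4 × 5 = 100 combinations over
[0.13, 0.17] × [0.74, 0.77] × [0.08, 0.12], step 0.01). A synthetic
multispectral generator (batch shifts, drift, gross outliers, ground truth
attached) makes the whole pipeline testable without any instrument data, and
an imaging path (Gaussian-mixture segmentation + feature extraction) turns
m × n × 18 cubes into feature vectors.

## Worked example

```r
library(uosdfs)

d   <- generate_dataset(generator_config(seed = 7))   # 65/48/114 samples
run <- run_pipeline(d, seed = 7)                      # tune + classify + evaluate

run$thresholds
#> $th_fd 0.17  $th_mr 0.77  $th_p 0.08     (0 validation errors)

print(run$confusion)
#> Confusion matrix (positive = spoiled)
#>          truth
#> predicted fresh spoiled
#>   fresh     102       4
#>   spoiled     0       8
#> sensitivity 100.0%  specificity 96.2%  accuracy 96.5%

print(run$bin_table)
#> Assignments per TVC bin (positive = spoiled)
#>           bin   positive      negative
#>       TVC < 2 4/106 (4%) 102/106 (96%)
#>      TVC >= 6 8/8 (100%)      0/8 (0%)
```

The grid search picked the sparsest zero-error operating point
(`th_fd = 0.17, th_mr = 0.77, th_p = 0.08`). On the contaminated test split,
all 8 spoiled samples are recognized (sensitivity 100%) and 102 of 106 fresh
samples are released correctly (specificity 96.2%); overall accuracy 96.5%.
`run$rates` shows the per-feature selection rates behind this: the four
informative NIR band means are selected for ~95% of test samples, every
pure-noise feature for 0%.

Per-sample selection is inspectable: `run$predictions$traces[[i]]` records
which features survived each cascade stage for test sample i, and
`selection_rates()` / `loo_training_selection()` aggregate these into
selection-rate histograms. `static_baseline()` provides the fixed top-k
counterpoint that the dynamic cascade beats under drift.

A thin command-line front end ships in `inst/cli/uosdfs.R`
(`simulate`, `extract`, `tune`, `classify`, `run`), e.g.:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/uosdfs.R", package="uosdfs"))')" run --seed 1 --out out/
```

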
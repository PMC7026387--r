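# deepsol

Deep residual convolutional networks for predicting aqueous solubility
(logS) of small molecules from 881-bit PubChem substructure fingerprints —
together with the data-curation pipeline, shallow fully-connected
baselines, training and cross-validation protocols, and the evaluation
metrics used in solubility QSPR work.

**Who it is for.** Computational and medicinal chemists who have tables of
experimental solubility values (mixed units, duplicated structures,
below-detection-limit entries) plus PaDEL-style fingerprint descriptor
files, and want a reproducible path from those raw tables to trained
regressors and the standard metric panel.

## The model

The regression target is logS = log10 of solubility in mol/L. The input is
a binary vector b ∈ {0,1}⁸⁸¹ of substructure keys. An N-parameter-layer
residual 1D CNN maps b to ŷ = logS:

- stem convolution (kernel 7) to 9 channels;
- (N−2)/2 pre-activation residual blocks `x + F(x)` of two kernel-3
  convolutions each, in three stages of 9 → 18 → 36 channels, stride-2
  downsampling and a 1×1 projection shortcut at each stage transition;
- a single fully connected output layer over the flattened final feature
  map.

So an N-layer model has N−1 convolutions plus one fully connected layer
(projection shortcuts are not counted); supported depths are 8, 14, 20,
26. Baselines: multilayer perceptrons (default 512-1024-2048-4096 hidden
units, dropout 0.5, L2 0.001).

Training minimises the negative coefficient of determination per
minibatch,

  −R² = −(1 − Σ(yᵢ−ŷᵢ)² / Σ(yᵢ−ȳ)²),

with Adam, early stopping on an inner validation slice, and full seed
determinism. Evaluation reports R², RMSE, the percentage of predictions
within 10-fold of experiment (|ΔlogS| ≤ 1), four-way solubility-category
accuracy (practically insoluble < 0.1 g/L, slightly soluble 0.1–10,
soluble 10–100, freely soluble ≥ 100), and bootstrap confidence intervals
(default B = 10,000).

## Worked example

Everything below is runnable without any download: the synthetic module
generates fingerprint datasets with a *planted* additive
substructure-contribution mechanism, so the full pipeline can be exercised
and its recovery quantified.

```r
library(deepsol)

# 1. Simulate 5,000 compounds: 40 active bits, noise 0.3 log units
truth <- synthetic_truth(n_active = 40, noise_sd = 0.3, seed = 71)
ds    <- generate_dataset(5000, truth)

# 2. 80/20 split, train a 14-layer residual CNN (~10 min on one core)
sp  <- split_train_test(5000, 0.2, seed = 71)
fit <- train_model(resnet_spec(14), fm_subset(ds$features, sp$train),
                   train_config(seed = 71, max_epochs = 35))

# 3. Evaluate on the held-out 1,000 compounds
te <- fm_subset(ds$features, sp$test)
ev <- evaluate_predictions(tibble::tibble(
  compound_id = te$ids, y = te$y, y_hat = unname(predict(fit, te)),
  molecular_weight = te$mw))
glance(ev)
#> # A tibble: 1 × 5
#>       n    r2  rmse pct_within_10fold category_accuracy
#>   <int> <dbl> <dbl>             <dbl>             <dbl>
#> 1  1000 0.869 0.400              98.3              90.1
```

`r2 = 0.869` means the network explains 87% of the held-out logS variance
— close to this dataset's analytic noise ceiling of 0.925
(`1 - noise_sd^2 / synthetic_moments(truth)$var`; no predictor can beat
it). `rmse = 0.400` log units is well under the factor-of-10 band, so
98.3% of test compounds are within 10-fold of their true solubility, and
90.1% land in the correct coarse solubility category.

Curation of a raw compound table (mixed units, duplicates, censored
entries) is one pipe:

```r
curated <- parse_compound_table("compounds.csv") |>
  canonicalize_and_key() |>   # canonical SMILES + InChIKey + MW (Open Babel)
  compute_log_s() |>          # units -> mol/L -> logS
  deduplicate()               # InChIKey collapse, median on conflicts
provenance(curated)           # every exclusion and conversion, logged
```

A shell interface wraps the same functions
(`inst/cli/deepsol curate|train|crossval|predict|evaluate|simulate`), each
run emitting a JSON manifest with config snapshot, seeds and input
digests.

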
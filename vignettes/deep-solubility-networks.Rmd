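---
title: "Deep residual networks for aqueous solubility prediction: models, protocols and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep residual networks for aqueous solubility prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepsol)
```

## The problem

Aqueous solubility is one of the first physicochemical properties screened
in drug discovery: a compound that cannot dissolve at assay or formulation
concentrations is difficult to develop regardless of its potency. The
quantity modelled here is logS — the base-10 logarithm of the saturation
concentration in mol/L at room temperature near pH 7. Typical drug-like
values run from about −8 (practically insoluble) to 0 or above (freely
soluble).

deepsol regresses logS from 881-bit PubChem substructure fingerprints: a
standardized binary vector in which each bit flags the presence of a
predefined chemical substructure. The working hypothesis behind the model
family is that solubility is driven by which substructures a molecule
contains and by local combinations of them — polar groups raise it, large
hydrophobic ring systems depress it — so an architecture with strong
local-feature learning (a 1D convolutional network sliding over the bit
vector) is a natural fit, and residual connections allow it to be deep
(14–26 parameter layers) without the optimisation problems of plain deep
stacks.

## The data model and curation pipeline

Experimental solubility tables arrive in heterogeneous units (μg/mL, mg/mL,
mg/L, g/L, mol/L). The pipeline normalises every record to logS in mol/L;
mass-based units need a molecular weight, which the chemistry backend (Open
Babel, via ChemmineOB) computes from structure when the table does not
supply it. Conversion of a mass unit without a molecular weight is a hard
error rather than a silent skip: dropping such records quietly would bias a
dataset toward whatever sources happened to report molar units.

Structural identity is enforced in two steps: SMILES are canonicalized by
the backend (canonical forms are toolkit-specific, so the contract is
internal consistency, not cross-toolkit identity), and InChIKeys derived
from the structures serve as the deduplication key. For duplicate groups
the sources may disagree on the measured value; solubility measurements
routinely scatter by a factor of 2–3 between laboratories. We keep a single
record carrying the **median** logS of the group — robust to one bad
measurement, and equal to the single value when all copies agree. Records
reported only as "insoluble below X" are kept with `censored = TRUE` and
excluded from regression metrics; discarding them entirely would hide the
information that the compound was measured at all, while imputing a value
would fabricate one.

Every decision — rejected row, excluded SMILES, removed duplicate — is
appended to a provenance log so that record counts reconcile exactly at
each stage: rows in = rows out + logged removals.

## The regression models

### Residual 1D CNN ("deeper net")

An N-parameter-layer network consists of:

* a stem convolution (kernel 7, stride 1) lifting the 1-channel bit vector
  to 9 channels;
* (N−2)/2 pre-activation residual blocks of two kernel-3 convolutions each,
  arranged in three stages of widths 9 → 18 → 36; the first block of stages
  two and three downsamples by stride 2 and doubles the width, with a
  1×1 projection shortcut carrying the skip path across the dimension
  change;
* one fully connected output layer producing the scalar logS.

N counts the stem, the block convolutions and the output layer — N−1
convolutions plus one fully connected layer. Projection shortcuts are
parameterised but conventionally not counted; they appear in the layer
audit with `counted = FALSE` so the arithmetic is checkable:

```{r audit}
tidy(build_resnet(resnet_spec(20)))
glance(build_resnet(resnet_spec(20)))
```

Valid depths satisfy (N−2) divisible by 6 with the default three stages:
8, 14, 20, 26. The depths 14–26 are the "deeper nets"; 8 is the shallow
ResNet baseline.

Three design choices deserve explanation, because the architecture family
leaves them open:

**Pre-activation blocks.** Each block computes
`x + conv(act(bn(conv(act(bn(x))))))` rather than applying an activation
after the addition. With the branch weights at zero a block is then *exactly*
its shortcut — identity where dimensions match, the projection where they
change. This is both the cleaner optimisation structure (the identity path
is unobstructed end to end) and a property the test suite verifies
numerically via `zero_residual_branches()`.

**Flatten head, not global average pooling.** Image ResNets pool the final
feature map over space before the classifier because image classes are
translation invariant. Fingerprint bits are *not* translation invariant:
bit 542 means one specific substructure, and an additive substructure
model assigns it a specific weight. Averaging over positions would make
the network's output a sum of position-agnostic local functions, which
cannot represent position-specific bit weights — the very mechanism the
synthetic-data generator plants and the recovery tests measure. The default
head therefore flattens the final 36-channel feature map and lets the single
fully connected layer see every position; `head = "gap"` remains available
for comparison.

**Batch normalisation on by default.** The architecture family does not
prescribe it; without it, training a 20-plus-layer stack on 0/1 inputs at
learning rates that converge in reasonable time is brittle. It is a
toggleable flag (`use_batch_norm`) so the ablation is one keystroke.

Weight initialization is fan-in-scaled uniform,
U(−√(6/fan_in), +√(6/fan_in)), the standard choice for ReLU stacks; the
scale is configurable. ReLU is the default activation, with sigmoid and
softmax available for comparison runs.

### Fully connected baselines ("shallow nets")

`dnn_spec()` declares plain multilayer perceptrons. The default is the
4-hidden-layer reference configuration used as a comparison point in the
solubility deep-learning literature: hidden sizes 512, 1024, 2048, 4096,
ReLU, dropout 0.5, L2 0.001. `hidden_sizes = 512` gives the 1-layer
baseline. Baselines are named by hidden-layer count, as is conventional
for DNN models.

## Training

The training objective is the negative coefficient of determination over
each minibatch:

−R² = −(1 − SSE/SStot),  SSE = Σᵢ(yᵢ−ŷᵢ)², SStot = Σᵢ(yᵢ−ȳ)².

For a fixed batch this is an affine function of the SSE, so minimising it
is least squares with a per-batch variance normalisation; a batch with zero
target variance falls back to SSE/n with a notice rather than dividing by
zero (hence the `batch_size >= 2` requirement). The `loss = "mse"` option
exists for comparison, and a property test verifies the two produce
identical full-batch gradient-descent trajectories after a learning-rate
rescaling by SStot/n.

The optimiser defaults — Adam at learning rate 3×10⁻³ with a plateau
schedule (×0.3 after five stalled validation epochs), decoupled weight
decay on the convolution and dense weight matrices (the AdamW
formulation; coefficient 1 for the residual CNN), batch size 64, at most
200 epochs, early stopping with patience 20 on an inner 10% validation
slice, best-validation weights restored — were selected by planted-signal
recovery on synthetic data: with a small in-gradient L2 penalty instead,
the 14-layer network memorises a 4,000-compound training set (training R²
0.99) while held-out R² stalls near 0.5, whereas decoupled decay plus the
annealing schedule carries held-out R² to within a few hundredths of the
analytic noise ceiling. The exact values used in the original modelling work are
not published, so ours are package defaults, documented and configurable,
not a claim about that work. Every random element (initialization,
validation slice, epoch shuffling, dropout) derives from one seed, so a
fixed seed reproduces a training history bit-for-bit on a single platform
with single-threaded BLAS.

Protocols: `split_train_test()` implements the 90/10 split (9,943 records
give 994 test / 8,949 train); `make_folds()` and `cross_validate()`
implement k-fold cross-validation with near-equal folds (9,943 in 10 folds:
seven of 994, three of 995), independently initialized per-fold trainings,
and min–max range reporting of R² and RMSE across folds, the conventional
reporting shape for this protocol. Fold assignment operates on rows sorted
by compound id, so shuffling the input table does not change the result.

## Evaluation metrics

* **R²** = 1 − SSE/SStot on the raw predictions (no refitting). It is the
  coefficient-of-determination form, which for free predictions can be
  negative without bound; reports sometimes display small values as "<0.2",
  which `format_r2()` reproduces as presentation only. (Some descriptions
  call R the Pearson correlation; the two coincide only for fitted linear
  models, and the formula implemented is the one above.)
* **RMSE** in log units.
* **Percent within 10-fold**: the share of compounds whose predicted
  solubility is within a factor of 10 of experiment. A factor of 10 in S
  is exactly one log10 unit, and the boundary is counted inclusively
  (|Δ logS| ≤ 1) — the defining phrase "within 10-fold" includes a
  10-fold error on its face.
* **Category accuracy**: agreement of the four-way classification
  practically insoluble (< 0.1 g/L), slightly soluble (0.1–10), soluble
  (10–100), freely soluble (≥ 100). Conversion from logS (mol/L) to g/L
  requires the molecular weight, which the curated record carries. Lower
  bounds are inclusive, resolving the tilde notation "0.1~10" one way and
  documenting it; boundary behaviour is tested exactly.
* **Bootstrap summaries**: B resamples (default 10,000) of (y, ŷ) pairs
  with replacement; mean, SD and percentile 95% interval per metric.
  Resamples with zero variance in the resampled y leave R² undefined;
  they are skipped and counted rather than propagating NaN.

## The synthetic-data generator

Real curated solubility sets with their fingerprints are not
redistributable here, so the generator plants a *recoverable* mechanism
with the statistical shape the models assume: logS = intercept + Σ wᵢbᵢ
(+ optional pairwise interaction terms) + Gaussian noise, over 881
Bernoulli bits with realistic density and optional block correlation
(adjacent bits co-occur, as real substructure keys do — ring-size keys,
halogen counts and the like come in runs).

Defaults, chosen once as a realistic emulation of a drug-like logS
dataset: 40 active bits with weights uniform in ±0.8 log units, intercept
−4, bit density 0.12, noise 0.5 log units (replicate-level experimental
scatter), logS clipped to [−10, 1], synthetic molecular weights uniform in
150–600 g/mol so category evaluation works. The signal variance under
these defaults is about 1 log² unit, giving datasets whose spread matches
curated logS collections.

What the generator does *not* emulate: real PubChem bit semantics, the
long-range bit correlations induced by chemical series, and the heavy
left tail of real solubility distributions. Passing recovery tests
therefore demonstrates that the implementation can learn a planted
additive substructure mechanism through the full pipeline — not that the
architecture will match published performance on literature data.

With zero noise and a purely linear mechanism, ordinary least squares on
the active bits recovers the planted weights to numerical precision
(n ≥ 2k identifiable design) — the generator's own correctness oracle.
With noise σ, no predictor can exceed the ceiling
R²* = Var(signal)/(Var(signal)+σ²); recovery runs are judged against that
ceiling, not against 1.

## Numerical choices

* Batch-norm statistics use the population variance with momentum 0.1 and
  ε = 10⁻⁵; evaluation mode uses the running statistics, so prediction is
  deterministic.
* The negative-R² batch guard triggers at SStot ≤ n·ε_machine.
* A trailing minibatch of size 1 is folded into the previous batch (batch
  variance must be definable).
* Non-finite training loss aborts with a diagnostic (learning rate, epoch,
  batch) rather than continuing with NaN weights.
* The conv/batch-norm compute core is compiled C++ (contiguous-window
  kernels); an R implementation of the identical computation ships in the
  package and the test suite asserts exact agreement between the two on
  every architecture variant, with finite-difference checks on top.
* Problem sizes in the test suite: unit tests run reduced widths (30-bit
  inputs, 3–7 channels); the full-scale recovery check trains a 14-layer
  network on 5,000 compounds of 881 bits for up to 35 epochs — the point
  by which the default schedule has reached its held-out plateau on this
  problem (roughly ten minutes on one desktop core).

## Known limitations

* No pH- or temperature-dependent modelling; the curation pipeline assumes
  upstream eligibility filtering (room temperature, ~pH 7).
* The PubChem fingerprint bit definitions are not reimplemented;
  fingerprints arrive from descriptor files (PaDEL dialect) or a pluggable
  provider.
* Censored records participate in curation and bookkeeping but not in
  regression metrics; no censored-likelihood fitting is attempted.
* Single-threaded determinism is the contract; multi-threaded BLAS may
  reorder floating-point reductions and change low-order bits of a
  training history.
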
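---
title: "Hybrid linear/neural QSAR modelling and virtual screening: methods"
author: "qsarscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid linear/neural QSAR modelling and virtual screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarscreen)
```

# The modelling problem

Ligand-based virtual screening starts from a table of compounds described
by real-valued molecular descriptors (constitutional, topological,
electrostatic, quantum-chemical) and a measured activity, here logIC50 —
the base-10 logarithm of the half-maximal inhibitory concentration in nM.
Lower logIC50 means a more potent inhibitor. Two regression models are
built on the same training data — a multilinear equation found by
best-subset search and a small feed-forward neural network — and both are
then applied to a large library of candidate compounds. Candidates are
ranked by the average of the two predictions, restricted to the region of
descriptor space where the models can be trusted.

`qsarscreen` implements that entire workflow on abstract descriptor
tables. It does not compute descriptors from structures: descriptor
generation (conformer search, semiempirical quantum chemistry) is a
separate, heavyweight stage performed by external software, and the
package treats its numeric output as the starting point.

# Descriptor-space reduction

Descriptor software typically emits several hundred columns, most of them
uninformative for any one target. Two filters reduce the space before any
model is fitted:

* **Variance filter** (`variance_filter()`, threshold `1e-4`):
  near-constant descriptors carry no usable signal and destabilize
  min-max scaling. Sample variance uses the n−1 denominator.
* **Activity-correlation filter** (`correlation_filter()`, `|r| > 0.2`):
  descriptors weakly correlated with logIC50 are dropped. The absolute
  value is deliberate — a strongly negative correlate is exactly as
  informative as a positive one, and fitted QSAR equations routinely
  carry negative coefficients — so the filter is sign-blind.

The composition order (variance first, then correlation) is enforced:
the correlation filter rejects zero-variance columns outright rather
than silently producing undefined correlations. Both filters are
idempotent.

Descriptors are then scaled with parameters frozen on the training set
(`scale_descriptors()`), min-max to [0, 1] by default; a z-score variant
is available behind the `method` switch for workflows that prefer
centring by the standard deviation. The same frozen parameters — never
refit — transform every later screening library, so out-of-range library
compounds simply map outside [0, 1]. Activities are mapped affinely onto
[−1, 1] (`normalize_activity()`), matching the output range of the
network's tanh output neuron; the inverse map is exact.

# The multilinear route

`fit_ols()` fits ordinary least squares with an intercept (always
included, never counted in the descriptor count k) and reports the full
conventional diagnostic set: coefficients B, standard errors, t = B/SE,
R², residual variance s² = RSS/(N−k−1), Fisher's
F = (R²/k)/((1−R²)/(N−k−1)), and the leave-one-out cross-validated R²_cv.
R²_cv is computed by the hat-matrix identity e₍ᵢ₎ = eᵢ/(1−hᵢᵢ), which is
algebraically equal to N refits with one compound left out each time; the
test suite verifies that equality to 1e-10 against an explicit refit loop.

**Best multilinear regression** (`bmlr_search()`) returns the best
k-descriptor equation for each k from 2 upward. All admissible pairs are
scored exhaustively at k = 2; each larger k extends the `beam_width` best
subsets of size k−1 by every admissible descriptor. Admissibility caps
the pairwise correlation between descriptors in one model at
`max_intercorrelation`. Within fixed k the best model is the one with the
highest R²; for fixed k and N the F statistic is a monotone function of
R², so selection by R² and by F coincide and no tie-breaking between the
two criteria is needed. Defaults — beam width 50, |r| cap 0.8 — are
design choices where practice only demands "non-collinear descriptors";
both are exposed in the configuration. With the default beam width the
search matches exhaustive best-subset enumeration on every synthetic
instance in the test suite (p = 10, k ≤ 4); the nested-model
monotonicity of R² in k is asserted for the exhaustive oracle only,
since a beam search does not guarantee it.

**Leverage reduction** (`leverage_reduce()`) iteratively removes
compounds whose hat value exceeds `threshold_multiplier · (k+1)/N`
(default multiplier 3, a standard convention), refitting after each pass,
and never reduces the data below a floor fraction (default one half).
This is the remedy applied when a statistically sound linear equation
cannot be obtained on a full, structurally heterogeneous set.

**ABC validation** (`abc_validate()`) estimates external predictivity in
a way that respects the activity distribution: compounds are sorted by
activity and dealt cyclically into three subsets (sorted ranks 1,4,7,…
form A; 2,5,8,… form B; 3,6,9,… form C — ties broken by original row
index, so the split is deterministic). The model is refitted, same
descriptors but re-optimized coefficients, on each pair AB, BC, CA and
predicts the held-out C, A, B. Per fold the fit R², the leave-one-out
R²_cv and the prediction R² are reported; the headline number is the
average of the three prediction R². Prediction R² is the squared Pearson
correlation between predicted and observed held-out activities —
matching the "average square correlation" convention — with the
1 − PRESS/SS formulation available behind `r2_pred_method = "press"`.

# The neural route

The regressor (`train_ann()`) is a fully connected feed-forward network
with one or two hidden layers and a single output neuron, hyperbolic
tangent everywhere (a linear output is available behind a config switch;
tanh is the default because targets live in [−1, 1]). Training is the
generalized delta rule: online per-pattern updates

Δw(t) = −η ∂E/∂w + α Δw(t−1),  E = ½(t − o)²,

with learning rate η and momentum α, pattern order reshuffled each epoch
from a deterministic per-epoch stream. The inner loop is compiled (Rcpp);
a pure-R reference implementation of the identical update is kept
internally and the two are required to agree to 1e-10 in the test suite.
Back-propagated gradients are checked against central finite differences
to 1e-6 as a standing property test.

Choices the update rule leaves open, and the package's defaults:

* **Initialization**: weights Uniform(−0.5, 0.5), biases zero, from the
  seeded stream. Training is bit-reproducible given the seed.
* **Early stopping**: after every epoch the RMS error on a held-out
  validation set is evaluated; the weights of the epoch with minimum
  RMS_val are restored at the end, and training halts once `patience`
  (default 50) consecutive epochs bring no improvement beyond
  `min_delta = 1e-5`. This operationalizes "stop when the validation
  error starts to rise" without reacting to single-epoch noise.
* **Validation split** (`train_val_split()`): compounds are sorted by
  activity and every step-th one (step 5 by default, 3 also
  conventional) goes to validation, so both subsets span the activity
  range. Applied to sets of 101, 133 and 151 compounds, the step-5 rule
  yields validation sizes 20, 26 and 30 — the sizes the published
  companion models report — which is why 5 is the default.
* **Divergence guard**: training aborts with a diagnostic if the
  training RMS exceeds ten times its initial value (only reachable with
  a linear output, since tanh bounds the error) or any output becomes
  non-finite.

**Input selection** (`select_inputs()`): descriptors are ranked by
single-descriptor R² against the activity and the top n (default 5) are
taken; then each selected descriptor in turn is tentatively swapped for
each non-selected one and the swap is kept when a short, fixed-seed probe
training run lowers the validation RMS. A sensitivity sweep of this kind
can be read either as ranking candidate inputs before training or as
perturbing a trained net; the implemented reading is the former, because
it is deterministic, cheap, and testable against planted ground truth
(the suite requires all five planted informative descriptors among 30
noise columns to be recovered).

# Applicability domain and screening

A model's predictions are only trusted inside the descriptor region it
was trained on. Per descriptor i the domain is the closed interval
[min_i − 0.3·range_i, max_i + 0.3·range_i] computed from the training
table (`compute_ad()`); a compound is inside (`check_ad()`) only if every
descriptor lies in its interval simultaneously. The intervals are closed
so that the extreme training compounds themselves pass; a zero-range
descriptor collapses to the point ± a small epsilon with a warning.

Screening libraries pass four prefilters (`prefilter_library()`), in
order: duplicate identifiers (first occurrence kept), records with a
missing descriptor value — the abstraction this package uses for
"unclear structural connectivity", a structure-level notion it cannot
evaluate —, molecular weight strictly above 600 amu (a record at exactly
600 survives), and records without purchasability information. Each
removal is counted against the first filter that triggered.

`consensus_screen()` predicts logIC50 with both models, averages the two
predictions, and ranks in-domain records ascending by the average —
lower predicted logIC50 ranks better, because the screen seeks potent
inhibitors. Whether a per-model rank consensus should supplement the
averaged score is an open question in the source workflow; the average
alone is implemented as the single ranking key, with both per-model
predictions retained in the output for inspection. Out-of-domain records
keep their predictions but never receive a rank. Ties break by compound
identifier, making the ranking a total order. `top_selection()` takes
the first n (default 100) ranked records, with an optional fractional
second cut (0.4 of a top-100 shortlist hands 40 compounds to
structure-based follow-up).

# The synthetic-data generators

Real descriptor tables for this workflow come from curated bioactivity
databases and quantum-chemical descriptor software; neither is
redistributable nor cheap to run. The generators replace them with data
whose ground truth is known exactly, so every downstream stage is
testable:

* `gen_linear_dataset()` draws descriptors Uniform(0, 10) — descriptor
  marginals are not constrained by any convention, so a flat,
  overridable default was chosen — and builds the activity as a known
  linear combination of chosen columns plus Gaussian noise.
  Collinear blocks are induced through a Gaussian copula: latent normals
  with equicorrelation 2·sin(πr/6) yield uniforms with Pearson
  correlation r, hitting the target within ±0.05 at n ≥ 100 while
  preserving the uniform marginals. Near-constant columns (variance
  ~1e-6) exercise the variance filter.
* `gen_nonlinear_dataset()` uses the fixed surface
  f(D) = 3·tanh((D₁−5)/1.5) + 0.2·(D₂−5)(D₃−5) + 0.2·D₄ — one
  saturating term, one interaction, one weak linear term. The
  saturation scale and interaction weight were set so that the best
  multilinear fit can explain only about two thirds of the response
  variance (population linear R² ≈ 0.65) while a small tanh network can
  reach ~0.98, giving the linear/neural comparison a decisive,
  construction-guaranteed gap.
* `gen_screening_library()` draws records inside given domain bounds and
  pushes exactly round(n·frac_outside) of them outside on at least one
  descriptor, planting disjoint sets of duplicate identifiers,
  missing-descriptor records, heavy records (MW > 600) and
  non-purchasable records so every prefilter count can be asserted.

One global integer seed drives everything; per-operation and per-epoch
sub-streams are derived deterministically, and generation restores the
caller's RNG state. What the generators do **not** emulate: real
descriptor distributions (heavy tails, discreteness of counts),
structure-induced correlation patterns beyond pairwise blocks,
activity-cliff behaviour, and assay noise that varies with potency.
Passing tests therefore demonstrate algorithmic correctness and
statistical behaviour under controlled conditions, not predictive
performance on experimental data.

# Benchmark conditions used by the test suite

The suite and the acceptance script run at sizes chosen to make the
statistical assertions sharp yet quick: parameter-recovery and subset-
recovery rates use 100 replicates of n = 150 compounds with noise SD 0.1
in logIC50 units (planted coefficients recovered within 3 SE in ≥ 95 %,
planted pair found in ≥ 90 %); oracle-equivalence uses 25 datasets with
p = 10 descriptors and k ≤ 4; the nonlinear benchmark is n = 150, eight
descriptors, noise 0.1, an 8-6-1 network trained with η = 0.05, α = 0.5
up to 2500 epochs (patience 300); the noiseless-linear convergence run
is n = 120 with a 3-4-1 network and the same η/α, reaching training RMS
< 0.05 (scaled units) well inside 5000 epochs; domain-truth agreement is
checked on 10,000 library records. Published training runs of this style
report η around 0.02–0.03 with small momentum on real descriptor sets;
the faster setting here reflects the cleaner synthetic surfaces, and the
epoch counts reported for real sets (1600–3500) are treated as
descriptive, not as reproduction targets.

# Numerical choices and degenerate inputs

* OLS uses a QR decomposition; rank deficiency is rejected naming the
  collinear columns rather than silently dropping them.
* Leave-one-out is undefined when any leverage equals 1; this is an
  error, not an NA, in `loo_r2()` (inside `fit_ols()` the R²_cv slot
  degrades to NA so that the rest of the diagnostics survive).
* `abc_validate()` refuses held-out subsets smaller than 3 compounds;
  correlation-based R² is meaningless below that.
* Ties: activity ties in `abc_split()` and `train_val_split()` resolve
  by original row order (stable sort); ranking ties in screening resolve
  by compound identifier; descriptor-ranking ties resolve by name.
* Serialization keeps full numeric precision (JSON written with
  unrestricted digits); models, bounds, scaling parameters and reports
  all round-trip through JSON with predictions identical to 1e-12.

# Limitations

The package deliberately stops at the ranked shortlist: no docking
hand-off formats, no binding-energy rescoring, no structure handling at
all. It implements plain OLS (no regularization, no robust standard
errors) and the classical delta rule (no adaptive optimizers) because
fidelity to that methodology — and testability of every one of its
steps — is the point.
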
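---
title: "Bioactivity-based read-across: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioactivity-based read-across: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(babra)
```

## The problem

Regulatory read-across predicts an in vivo toxicity endpoint for a
data-poor target chemical from tested analogs. Structure-based analog
selection breaks down on activity cliffs: compounds that are nearly
identical chemically but act through different biology. `babra` selects
analogs by *biological* similarity — agreement of high-throughput in vitro
bioactivity profiles — and treats structural similarity as an optional
additional weight.

## The similarity model

Given a compound × assay matrix X (binary hit-calls or continuous
potencies both work; trees are invariant to monotone feature scaling), an
unsupervised random forest yields a proximity matrix:

1. X is labeled class 1. A synthetic class 2 of the same size is created by
   resampling each column of X independently with replacement. Marginals
   are preserved; the dependency structure between assays is destroyed.
2. A two-class ensemble of CART-style trees (Gini splits, bootstrap of the
   stacked 2n rows, `mtry` random features per split, grown to
   `min_leaf = 1`) learns to separate the classes, which it can only do by
   exploiting between-assay correlation.
3. Every *original* compound is dropped down every tree; P[i,j] is the
   fraction of trees in which i and j share a terminal node. The diagonal
   is exactly 1 and synthetic rows never enter P.

Counting uses all trees for all compounds (the classic all-cases
proximity); an out-of-bag-only variant is available via
`proximity_config(oob_only = TRUE)`, which normalizes each pair by the
number of trees where both compounds are out-of-bag. The tree learner is
delegated to `ranger`, which exposes per-tree terminal-node identifiers for
arbitrary rows; node ids are opaque tokens comparable within a tree only.

**Reproducibility convention.** Bootstrap draws depend on row order inside
the learner, so `compute_rf_proximity()` canonicalises rows to sorted
compound-id order before fitting (the synthetic class is drawn on the
canonical order too) and maps the result back. Under a fixed seed the
proximity matrix is therefore invariant to input row permutation — a
property the test suite checks bit-for-bit. A master seed derives the
synthetic-class seed and the forest seed; all fits are single-threaded.

**Missing assay data** are resolved before the synthetic class is drawn, so
both classes share one feature support. `median-impute` substitutes the
assay median of observed cells; `indicator-augment` additionally appends a
0/1 missingness column per assay, letting trees split on the missingness
pattern itself. A column with no observed values is an error, named.

## Prediction

With neighbor outcomes A_i ∈ {0, 1}, proximities P_i and Tanimoto
similarities S_i:

* BaBRA: A_pred = Σ P_i A_i / Σ P_i
* St.BaBRA: A_pred = (Σ P_i A_i + Σ S_i A_i) / (Σ P_i + Σ S_i)

Neighbor candidacy requires a known label and ranking weight ≥ τ; the top
k by weight are kept (ties broken by ascending compound id, so results are
deterministic). Zero eligible neighbors or zero total weight yields a
NON_EVALUABLE result rather than a number. A_pred ≥ `call_cutoff` (default
0.5, boundary inclusive) is called POSITIVE.

Which similarity orders the kNN space when both are in play is genuinely
open; the package defaults to ranking by the combined weight P + S —
matching the denominator of the St.BaBRA equation, so the compounds that
dominate the average are the ones selected — with `rank_by = "proximity"`
as the alternative. Setting S ≡ 0 reduces St.BaBRA to BaBRA exactly, a
tested identity. Compounds with UNKNOWN labels are never neighbors but are
always predictable: filling such gaps is the purpose of read-across.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_trees` | 500 | ensemble size; 10,000 is customary for production-scale proximity work, 100–500 is ample at the n ≤ a few hundred scale used here |
| `mtry` | ⌊√p⌋ | features per split |
| `min_leaf` | 1 | terminal node size; 1 maximizes proximity resolution |
| `k` | 5 | neighbors averaged |
| `min_weight` (τ) | 0 | similarity floor for candidacy, in [0, 1] |
| `call_cutoff` | 0.5 | POSITIVE threshold on A_pred (inclusive) |
| `min_overlap` | 4 | mutually observed assays needed before a trinary-profile agreement is scored |

## Evaluation protocol

In vivo endpoints are typically unbalanced; `balance_dataset()` keeps the
whole minority class plus an equal-size seeded sample of the majority.
`loo_evaluate()` predicts each labeled compound with its own label withheld
(an internal assertion guarantees a compound never appears among its own
neighbors), tallies the confusion matrix over evaluable predictions only,
and reports sensitivity, specificity and balanced accuracy; non-evaluable
compounds are counted and reported, never silently dropped. The proximity
matrix is computed once on the full compound set and reused across folds:
it is unsupervised with respect to the endpoint, so no label leakage
occurs.

Significance is assessed by label permutation:
p = (1 + #{BA_perm ≥ BA_obs}) / (1 + n_perm), labels shuffled over labeled
compounds only. Because candidacy and ranking weights do not depend on
label *values*, the neighbor sets are invariant under permutation, and each
permuted evaluation reduces to one row-normalized matrix–vector product —
the implementation precomputes that weight matrix; a unit test verifies
exact agreement with naive re-evaluation. An exact one-sided binomial test
against 50% accuracy on balanced data is provided as an independent
cross-check. `parameter_sweep()` runs the full (k, τ, mode) factorial and
selects the best balanced accuracy, preferring smaller k then larger τ on
ties — the simpler, more conservative model.

## The synthetic-data generator

`generate_dataset()` emulates the structure that makes bioactivity-based
read-across work: each compound carries one latent mechanism of action;
assays linked to that mechanism fire with probability 0.9 versus a 0.05
background; calls are flipped with a symmetric noise rate and masked
missing at a configurable rate (the pre-masking trinary view is emitted
alongside the numeric matrix); fingerprints contain mechanism-specific
informative bits over random background bits, optionally behind a shared
scaffold; the endpoint is POSITIVE for compounds whose mechanism belongs
to a designated toxic subset, with label flips modelling in vivo
variability. One mechanism per compound keeps ground truth crisp; mixture
membership is a noted extension. Mechanisms are drawn i.i.d. uniformly by
default; `balanced_mechanisms = TRUE` assigns exact equal-size clusters
for designs where the generative neighborhood size must be controlled.

Frozen presets: `signal` (200 compounds × 40 assays, 4 mechanisms, 2
toxic, 5% call/label noise — strong recoverable signal), `null` (same
shape, no toxic mechanisms, label noise 0.5, so labels are a fair coin),
`two-cluster` (60 compounds, 2 clean clusters), and `activity-cliff` (a
96-bit shared scaffold plus dense uninformative bits make Tanimoto
similarity blind to the mechanism that drives both bioactivity and
toxicity).

What the generator does *not* emulate: real assay identities or AC50
distributions, correlated assay technologies, multi-mechanism compounds,
and structured (non-random) missingness. Passing tests demonstrate that the
machinery recovers planted signal and stays calibrated under a true null —
not that any particular real endpoint is predictable at a given accuracy.

## Validation design and problem sizes

The test and acceptance workloads are sized for a single CPU: proximity
oracle checks at n = 8, T = 25; signal recovery at n = 200, T = 500, k = 5,
τ = 0 (balanced accuracy ≥ 0.85 expected); null calibration over 200
replicate datasets with 199 permutations each (mean BA within 0.5 ± 0.10
and a KS check that p-values are approximately uniform); neighborhood-size
recovery over 20 seeds with eight 7-compound clusters (six true peers per
compound, so the swept k should average 6 ± 2 — noise rates of 0.1 on
calls and 0.15 on labels make single-neighbor voting unreliable and
cross-cluster averaging harmful, which is what gives the sweep a real
optimum to find); and a 20-seed sign test that bioactivity ranking beats
structure-only ranking on activity-cliff data.

## Numerical choices and degenerate inputs

* Tanimoto of two all-zero fingerprints is 0 by convention (never NaN), so
  weighted sums stay finite; an all-zero fingerprint's diagonal entry is 0
  and a warning names the compound.
* Weight ties at rank k are broken by ascending compound id; duplicated
  ids are rejected at read time with the offending id named.
* Floats are serialized with 12 significant digits; write-then-read is the
  identity within 1e-12 relative error, exact for integers and strings.
* The permutation p-value floor is 1/(1 + n_perm); reports assert
  BA = (sens + spec)/2 on emission.

## Known limitations

Proximity forests at the default settings are O(T · n log n) per fit and
the LOO protocol reuses one fit, so very large chemical libraries will want
fewer, deeper-subsampled trees. Continuous-endpoint regression (predicting
effect levels as quantities) is out of scope: the engine classifies
endpoint presence. Structure handling is deliberately thin — fingerprints
arrive as bit-vectors or via a user-supplied SMILES fingerprinter callback;
no SDF parsing or descriptor generation is included.
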
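---
title: "Quality control of slide preparation pipelines from nuclei feature distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of slide preparation pipelines from nuclei feature distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slideqc)
```

## The model

`slideqc` treats a whole-slide-image preparation pipeline (WSI-PP) as a
generator of nuclei feature distributions. The processing pipeline that
precedes analysis already emits, per segmented nucleus, a vector of
scalar morphometric features (color, chromatin, texture, shape) plus a
debris flag and slide coordinates. A batch of `n_wsi` slides is reduced
to an `n_nuc x n_feat` feature matrix by composable nuclei selection,
then to a column-stochastic `n_bin x n_feat` matrix of per-feature
histograms on a shared `[0, 1]` scale. All subsequent quality reasoning
happens between such histogram matrices.

The core assumptions are:

* a preparation change expresses itself as a change in the *marginal*
  distribution of at least one nucleus feature (joint, multivariate
  drift that leaves every marginal untouched is invisible);
* the per-nucleus features are informative enough that distinct
  preparations are separated by some feature's distribution;
* reference and validation batches of the same pipeline are exchangeable
  draws of its production.

### Distances and their codomain

Three per-feature distances ω are offered, all bounded in `[0, 1]`:
1-Wasserstein on the bin centers (computed as the mean absolute
cumulative-sum difference scaled by bin width; its maximum on `n_bin`
bins is `(n_bin-1)/n_bin`), the Bhattacharyya coefficient in its
Hellinger form `sqrt(1 - BC)`, and the Jensen–Shannon distance with
base-2 logarithms. The Hellinger form is a deliberate choice: the raw
`-log(BC)` divergence is unbounded, while the weighted comparisons
downstream require a `[0, 1]` codomain. Aggregators g are max, mean and
median; max is the interpretable one, since the final distance is then
decided by a single feature which is reported as the attribution. (A
minimum aggregator is deliberately not offered: it would be near zero
whenever any single feature matches, defeating the constraints.)

### Weights, compatibility, quality

Each reference pipeline is a tuple `(R_i, P_i, alpha_i)`. The weight
`alpha_i` is the smallest distance from `R_i` to any *foreign*
validation pipeline represented under `R_i`'s reduction; by
construction every validation batch then satisfies the dissimilarity
constraint, and only the diagonal constraint (own validation batch
closer than the weight) can fail — that failure is the calibration
alert. Scoring returns the signed weighted distances, the compatibility
(fraction of constraints satisfied) and the quality
`Q = beta*Q_similar + (1-beta)*Q_dissimilar`, all bounded.

`beta` defaults to 0.7. A pure-dissimilarity score (`beta = 0`) tracks
the same trends but saturates when a batch is far from every reference;
`beta = 1` ignores the other references entirely. 0.7 weights the
similarity term enough that a drift away from the tested reference
dominates the score, while still rewarding separation from the other
references.

### A note on strict compatibility at the decision boundary

The minimum in the weight definition has a structural consequence worth
understanding before using `best_reference()` for hard assignment. For
the pipeline that *sets* reference j's weight (the arg-min), a fresh
batch is statistically exchangeable with the validation batch that
defined `alpha_j`; its raw distance to `R_j` therefore falls below
`alpha_j` with probability one half, and the strict constraint
`d_j >= 0` flickers. Summing arg-min in-degrees over pipelines bounds
the expected strict-assignment rate well below 1 (about 1/2 to 2/3
depending on which pipelines are each other's nearest neighbours),
independent of sample sizes or separation — the effect is a pure
exchangeability argument and does not shrink with more nuclei. The
package therefore treats compatibility as a conservative alarm and the
quality measure as the operative monitoring signal; the acceptance
suite measures the strict assignment rate honestly rather than
papering over it.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_bin` | 100 | Histogram bins on the normalized `[0, 1]` scale. Fine enough to resolve shifts of a few percent of the feature range at 10^3–10^4 nuclei, coarse enough that bins are well populated. |
| `n_wsi`, `n_nuc` | grid values | Slides per batch and total nuclei extracted; the per-WSI quota is `floor(n_nuc / n_wsi)`. |
| `intern_tau` | absent / 0.2 / 0.4 | Elliptic interior filter: keeps nuclei inside the centered ellipse with full axes `tau * width`, `tau * height` (the literal reading of "axes a percentage of width and height"). Avoids the poorly segmented clusters centrifugation leaves at slide edges. |
| `use_distrib` | off/on | Spatially stratified sampling on a `g x g` grid, `g = ceiling(sqrt(quota))`, cells visited round-robin with per-cell shuffling. Caps cluster oversampling. |
| `use_debris` | off | Removes debris-flagged rows before anything else. Not part of the searched grid. |
| `omega`, `aggregator` | wasserstein, max | See above. |
| `sel_method`, `n_sel` | none (all features) | One-versus-all chi-squared (lowest p-values) or greedy mRMR (F-statistic relevance over mean absolute Pearson redundancy, the FCQ quotient form). "No selection" is a single configuration with the identity reduction. |
| `beta` | 0.7 | Quality balance. |
| `seed` | — | All sampling flows from explicit seeds; identical inputs are bit-reproducible. |

Numerical conventions: histogram bins are half-open with a closed last
bin, so the upper normalization bound itself is counted; values outside
the reference range are dropped before binning but lower the
normalization count; a degenerate or fully out-of-range feature becomes
a uniform column with a warning rather than an error, keeping the
distance defined while surfacing the anomaly; chi-squared scores are
computed on the non-negative min-max-normalized class totals with one
degree of freedom; the mRMR redundancy denominator is floored at 1e-12;
all ties (p-values, importances, objective ranks, best-reference
quality) break to the lowest index or enumeration order for
determinism.

## Grid search and refinement

The searched space crosses the parameter values above: 3 slide counts,
3 nucleus counts, 6 nuclei-selection compositions (3 interior options
times the sampler toggle, the empty composition — plain random sampling
— being a legal value), 3 distances, 3 aggregators and 9
feature-selection configurations (2 methods x 4 finite `n_sel` plus the
single no-selection configuration), with one seed: 4374 combinations
(`enumerate_grid()`).

Step 1 keeps the valid combinations (accuracy 1: every diagonal
constraint holds; of the two printed forms of the accuracy only the
normalized diagonal-indicator form makes "valid iff A = 1" coherent, so
that form is implemented). Step 2 keeps the
`min(k1, ceiling(error_fraction * n_valid))` lowest-error combinations,
with `k1 = 150` and `error_fraction = 0.05` by default — on 2860 valid
combinations this yields 143. The fraction is exposed because on a
deliberately reduced grid (tens of combinations) a 5% cut collapses the
candidate set to a single row; exploratory searches set
`error_fraction = 1` so the cap `k1` alone binds. Step 3 ranks by
`T = 1 - E + H`, where `H` sums the per-parameter value frequencies
computed over the step-2 set (eight parameters, the nuclei-selection
composition counting as one), and keeps the top `k2 = 20`. Refinement
re-evaluates each survivor under fresh seeds (tests use 10 for a
practical runtime; the procedure itself is seed-count agnostic) and
keeps those valid for every seed. An empty valid set or an empty
refined set raises a QC alert: the reference and validation sets, or
the processing pipeline, should be reconsidered.

The error metric normalizes each column of the cross-distance matrix to
`[0, 1]` and takes one minus the worst margin by which a diagonal
undercuts its column's foreign entries; degenerate columns (all
distances equal — which happens when a bounded distance saturates for
every pipeline) are zeroed with a warning.

`retain_module()` implements the final retention step: candidates are
scanned in priority order (seed-stable survivors, then the
objective-filtered set, then the error-filtered set, then the valid set
by error) and the first whose calibrated module has weights strictly
inside `(0, 1)` is kept. A zero weight means two pipelines are
indistinguishable (merge them with `merge_references()`, which excludes
the merged pair's mutual distances from the weight minima without
pooling their representations); a saturated weight of exactly 1 —
which the bounded Jensen–Shannon and Hellinger distances reach on
disjoint supports — leaves the quality coefficient `alpha/(1-alpha)`
undefined, so such modules are flagged and skipped.

## The synthetic cohort generator

Real nuclei tables from clinical laboratories are proprietary, so the
generator is a first-class, tested module rather than a fixture. A
pipeline profile fixes, per feature, a two-component mixture of
truncated Gaussians (truncation symmetric at 4 standard deviations, so
mixture moments stay closed-form) translated by a per-feature offset
drawn reproducibly from the profile seed and scaled by `separation`.
Two profiles therefore differ by pure location shifts — the dominant
signature of stain-intensity and scanner changes — and the analytic
inter-profile Wasserstein distance equals the offset gap, which the
tests exploit as an oracle. Spatial structure emulates centrifugation:
a configurable fraction (default 0.3) of nuclei is placed in an
elliptic annulus hugging the slide border, making the interior filter
consequential. Debris rows (default rate 0.05) draw features from a
wider single-component law, making the debris filter consequential.
Feature values are left un-normalized on their abstract scale;
normalization happens only in representation, so out-of-range handling
is exercised.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: shape changes beyond location
(variance or modality drift), correlated multi-feature drift, per-slide
random effects (all slides of a profile are exchangeable), realistic
feature scaling of any concrete feature extractor, or scanner-specific
artifacts. Conclusions about detection *power* on real corpora require
real corpora.

Problem sizes in the test and acceptance suites are scaled to desk
hardware as the package's own choice of study size: cohorts of 2–4
pipelines, 4–10 slides per batch, 100–1000 nuclei per slide, 6–15
features, reduced grids of 16–48 combinations with 10 refinement
seeds, and 100 held-out assignment trials. The enumeration, ranking
and constraint logic are size-free; the stochastic checks state their
Monte-Carlo tolerances explicitly.

## Known limitations

* Marginal histograms only; multivariate transport is out of scope.
* Strict compatibility is conservative at the weight boundary (see
  above); use quality trends for monitoring and `merge_references()`
  when two references are near-clones.
* The chi-squared selector's contingency construction for continuous
  features (class totals of normalized values) is one standard
  realization; other binnings would rank differently.
* Stream scoring cuts contiguous, non-overlapping batches and drops a
  trailing remainder with a warning; no sliding windows.
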
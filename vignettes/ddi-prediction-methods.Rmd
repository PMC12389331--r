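---
title: "Similarity-based DDI prediction: model, conventions and limits"
author: "ddipredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based DDI prediction: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddipredict)
```

## The model

`ddipredict` implements a guilt-by-association screen for drug–drug
interactions (DDIs). Its central assumption is transferability of
interaction evidence through similarity: if drug *a* is known to interact
with drug *k*, and drug *b* resembles *k* — chemically, in its molecular
targets, its side-effect profile, its pathways, the interactome
neighbourhood of its targets, or in which drugs it is already known to
interact with — then (*a*, *b*) is a plausible interaction. The model is
purely associative: it does not represent mechanism, dose, or direction of
effect, and every prediction it makes is a hypothesis for pharmacological
triage, not a clinical claim.

Formally, the known interactions form a symmetric binary matrix `M1` over
the `n` catalog drugs (zero diagonal). Each of six features assigns every
drug a finite token set; pairwise Tanimoto similarity

$$T(A,B) = \frac{|A \cap B|}{|A \cup B|}$$

yields a per-feature similarity matrix `M2`. Evidence is propagated as
`M3 = M1 · M2'` (with `M2'` the similarity matrix with its diagonal forced
to zero), symmetrized by the elementwise maximum and rescaled by its global
maximum. The six per-pair scores are standardized and collapsed onto their
first principal component, which after sign orientation and min–max
rescaling is the unified score in `[0, 1]`. Known pairs' unified scores
define a third-quartile novelty threshold; unknown pairs strictly above it
are called candidate novel DDIs.

## The six features

* **CHEM** — chemical fingerprint bits. The pipeline accepts precomputed
  bit assignments, or derives them from SMILES via
  `smiles_to_fingerprint()`: all linear atom/bond paths of 1–7 atoms
  (molecule parsed with ChemmineR), each hashed into one of `n_bits = 1024`
  buckets. The fingerprint is deliberately pluggable because no single
  encoding is canonical; any bit-set representation works.
* **TECT** — targets, enzymes, carriers and transporters merged into one
  set. They are one biological statement ("shared molecular entities"), and
  merging keeps the feature count at six; tokens should be namespaced
  (`target:...`, `enzyme:...`) by the data preparer to avoid collisions.
* **ADE** — adverse-event terms, treated as opaque tokens (no ontology
  mapping).
* **PATHWAY** — pathway memberships, opaque tokens.
* **INTERACTOME** — each drug's protein targets expanded to every protein
  within graph distance `radius` (default 1) in the PPI network, then
  compared by Tanimoto. "Proximity in the interactome" has no unique
  formalization; the neighbourhood expansion keeps this feature
  commensurable with the other set-based features, and `radius` is exposed
  (0 reduces it to plain shared-target similarity).
* **IPF** — the interaction profile fingerprint: the set of a drug's known
  partners, taken from the rows of `M1`. Because it derives from `M1`, it
  is rebuilt from the *masked* matrix inside every cross-validation fold;
  the other five are static and cached.

## Numerical conventions

These choices make results deterministic across runs, platforms and
eigen-solvers; they are asserted by the test suite.

* **Empty sets.** `T(∅, ·) = 0`, and a featureless drug's `M2` diagonal is
  0 (not 1). Drugs missing from a feature source stay in the catalog with
  empty sets — all matrices share one index — but can never gain
  similarity-driven score from data they do not have.
* **Zeroed similarity diagonal before propagation.** Without it, every
  known pair would score itself through self-similarity
  (`M3[i,j] ≥ M1[i,j]`), and cross-validation would be circular.
* **Symmetrization by elementwise maximum**, because DDIs are unordered
  and evidence from either endpoint should count; **normalization by the
  global maximum** (not per-row), preserving relative evidence between
  high- and low-degree drugs.
* **PCA.** Columns are standardized; zero-variance columns are dropped
  with a warning (all-constant input is an error). The PC1 sign is fixed
  by requiring non-negative correlation with the row mean of the
  standardized columns (falling back to the first retained column), so
  "higher = more evidence". Scores are min–max rescaled to `[0, 1]`.
* **Quantile.** The threshold is the type-7 (linear interpolation)
  75th percentile of known-pair unified scores: `q3_threshold(c(0,1,2,3))`
  is 2.25. Novelty uses strict inequality (`score > threshold`). Note that
  with interpolated quantiles the count of values strictly above the
  threshold is bounded by `(n + 3) / 4` — i.e. a quarter up to one order
  statistic of slack, not a hard 25% for every sample size; ties only
  lower it. The threshold is computed from the full-data fit over known
  pairs (not from pooled cross-validation scores), which is the
  deterministic choice for calling novel pairs from the final model.
* **Pair order.** Unordered pairs are always keyed `drug_a < drug_b`
  (lexicographic), catalogs are sorted lexicographically regardless of
  file order, and output rows sort by descending score with pair-id
  tie-breaks. Written scores carry 12 decimal digits, making reruns
  byte-identical.
* **Youden operating point.** Cutoffs scan midpoints of adjacent distinct
  scores (plus sentinels beyond the extremes); ties in *J* resolve to the
  larger cutoff.

## Cross-validation protocol

`make_folds()` shuffles known pairs with a seed into `k = 10` near-equal
folds and samples one non-interacting pair per positive (ratio
configurable) without replacement. Sampled negatives, not the full
non-pair enumeration, keep the evaluation `O(positives)` while leaving the
AUROC estimate unbiased. For each fold, `masked_scores()` zeroes the
fold's positives in `M1`, asserts the mask took (the leakage guard),
rebuilds IPF and all six `M3`, reruns the PCA, and scores the fold. AUROC
uses the Mann–Whitney formulation with ties counted one half; sensitivity
and specificity are reported at the pooled Youden cutoff.

## The synthetic universe

`generate_universe()` emulates the statistical structure the method
assumes, so the whole pipeline is testable without licensed database
snapshots. Drugs are assigned round-robin to `n_clusters = 8` clusters;
each cluster draws a prototype token set (`prototype_set_size = 12` from
`tokens_per_kind = 200`) per feature kind, and each drug copies its
cluster's prototypes with per-token mutation at `token_flip_rate = 0.05`
(a flipped token is dropped or replaced with equal chance, so flip 0 gives
within-cluster Tanimoto exactly 1). Interactions are pairwise Bernoulli —
`within_cluster_ddi_prob = 0.6`, `cross_cluster_ddi_prob = 0.02` — and
20% of the sampled positives (`holdout_fraction`) are moved to a held-out
truth list that never reaches the visible files. The PPI network is a
cluster-partitioned random graph over the TARGET token universe (edge
probability 0.3 within a partition, 0.01 across — chosen once as a
plausibly modular interactome). Interaction descriptions are drawn from
class-tagged DrugBank-style templates so the effect classifier can be
benchmarked with known ground truth. A quarter of drugs
(`wrhd_fraction = 0.25`) are flagged as reproductive-health drugs with
one or two of the seven reproductive group labels — enough WRHD rows for
the reporting tables to be meaningful at `n_drugs = 120`. One master seed
drives per-component sub-streams at fixed offsets, so adding a component
never perturbs earlier draws and a written `params.yaml` regenerates the
identical universe.

What the generator does *not* emulate: realistic chemistry (CHEM tokens
are abstract bits, not substructures of real molecules), heavy-tailed
interaction degree distributions, correlated feature missingness, or
biased reporting of known DDIs. Passing the synthetic recovery tests shows
the pipeline's machinery is sound and leak-free; it does not certify
performance on any real database export.

### What recovery can and cannot reach

In the planted model, whether two drugs interact is — by construction —
conditionally independent of everything else given their cluster
co-membership. The best possible ranking therefore scores a pair only by
whether it is within-cluster, and its cross-validated AUROC is bounded by
the class mixture, not by model quality: with the default parameters
roughly a fifth of the positives are cross-cluster (pure noise), a few
percent of sampled negatives are within-cluster (indistinguishable from
masked positives), and held-out truth pairs sit unlabeled in the negative
pool. Working through the mixture puts the optimum near 0.87, which is
where the pipeline lands (see `scripts/acceptance.R` output); the
signal-free control (flip 0.5, equal within/cross probability) sits at
0.5 as it should. Raising the measured AUROC further would require making
the synthetic world easier, not the method better, so the generator
defaults stay put.

## Reporting conventions

Per-drug discovery rate is
`100 · new / (known_predicted + new)`, rounded to two decimals — the
formula that exactly reproduces the six mutually consistent published
worked examples used in the tests; reference tables of this kind also
contain rows no single formula reproduces, which we document rather than
chase. Effect classification applies ordered, case-insensitive keyword
rules with adverse-event phrases first ("risk or severity …" wordings
often contain pharmacokinetic vocabulary), then PK ("metabolism", "serum
concentration", "absorption", "excretion"), then PD ("therapeutic
efficacy", "efficacy", "activities"); anything else is `UNCLASSIFIED`.
The keyword lists are configuration (`EFFECT_KEYWORDS`), not code. In
per-drug tables a novel DDI counts once for each endpoint drug; in group
tables once for each group an endpoint belongs to, so bridging pairs
appear in both groups and disjoint groupings sum to at least the total
novel count.

## Problem sizes used by the tests

Unit and property tests run on instances of 2–50 drugs with brute-force
oracles (triple-loop propagation, concordant-pair AUROC counting,
elementwise Tanimoto double loops); pipeline and recovery tests use
40-drug/4-cluster universes, and the acceptance checks use the default
120-drug universe over five seeds — sizes at which every scientific claim
in the suite is checkable exactly in seconds.

## Known limitations

* Predictions inherit every bias of the input annotations; drugs with
  sparse feature data are systematically under-scored (by design — the
  empty-set convention prefers false negatives over fabricated evidence).
* PC1-only integration assumes the six evidence channels mostly agree;
  genuinely orthogonal evidence in later components is discarded.
* Scores are ranks, not probabilities: no calibration is attempted, and
  the third-quartile threshold is a screening convention, not an error
  control.
* The effect classifier is keyword-based and English-only.
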
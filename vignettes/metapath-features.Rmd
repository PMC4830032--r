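---
title: "Meta-path topological features for drug-target link prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-path topological features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapathDTI)
```

# The model

## Semantic network and adjacency contract

The network is typed: 9 node types (compounds, proteins, ChEBI types,
substructures, side effects, diseases, GO annotations, pathways, tissues)
and 12 edge types `A1`–`A12`, each stored as a sparse 0/1 adjacency matrix
— 1 for an observed link, 0 for an unobserved one. Every relation is
traversable in both directions; the reverse relation is *defined* as the
transpose of the forward adjacency, so no reverse matrices are stored.

Three edge types connect a node type to itself: protein–protein interaction
(`A6`) and the two similarity neighboring links (compound 2D-structural
similarity `A11`, protein sequence similarity `A12`). These are stored
symmetric with a **zero diagonal**. Self-similarity is a genuinely open
modeling point — similarity data sources do not always say whether an
entity neighbors itself — but a unit diagonal on `A11` would let every
compound reach its own targets through the
compound–similar–compound–binds–protein path, trivially leaking the
prediction target. We therefore never store self-loops on same-type edge
types; the edge-list reader drops them with a warning.

Duplicate edge rows collapse to a single 1 (the adjacency is boolean), and
`remove_links()` is copy-on-write so one base network can serve many
leakage-controlled experiments.

## Meta-paths and commuting matrices

A meta-path is an ordered sequence of oriented edge-type steps whose node
types chain: the oriented target type of step *k* equals the oriented
source type of step *k* + 1. Its commuting matrix is the ordered sparse
product of the oriented adjacencies, and entry (*i*, *j*) counts the
meta-path's **walk** instances from compound *i* to protein *j*.

*Walk semantics are deliberate.* Matrix products count walks, which may
revisit nodes and links (e.g. the shared-target path
binds → bound-by → binds counts the walk c–p′–c′–p even when c′ = c). The
field's vocabulary says "path instances", but the computation everyone
performs is the product; the package's independent test oracle
(`brute_force_walk_count()`, plus a row-wise walk enumerator in the test
helpers) enumerates walks one at a time, explicitly allowing revisits, and
the oracle-equivalence property is tested over random networks for the full
catalog.

Counts accumulate in doubles, exact below 2^53; on realistic networks
commuting-matrix entries reach ~10^7, so there is no overflow headroom
concern, and the oracle equality checks would catch any.

When a meta-path's semantics name several matrices in prose (e.g. "the
product of the binding, compound-similarity and protein-similarity
matrices"), the multiplication **order** is always the unique
type-compatible walk order with compounds on the rows; the packaged catalog
stores explicit oriented step sequences, so no ambiguity survives parsing.

## The packaged catalog and the enumeration grammar

The default catalog has 51 compound→protein meta-paths: 4 of length 2, 11
of length 3, 36 of length 4. Paths longer than 4 steps are excluded — long
indirect connections accumulate randomness faster than signal. A literal
exhaustive walk over the schema yields many more than 51 type-compatible
compound→protein paths of length ≤ 4, so the package reconstructs the
catalog with a constraint grammar (`preset = "slap51"`):

* form 1: `[compound neighborhood] [compound similarity] binds
  [protein expansion] [protein neighborhood]`
* form 2: `[compound neighborhood] treats caused-by [protein neighborhood]`

where the compound neighborhood is empty, a compound–X–compound loop
(X ∈ ChEBI type, substructure, side effect, disease) or binds·binds-back;
the protein expansion is empty, interaction or protein similarity; and the
protein neighborhood is empty or a protein–Y–protein loop
(Y ∈ GO annotation, pathway, tissue, disease). Whether the original
catalog was produced by such constraints or curated by hand is not
documented anywhere we know of; the package only guarantees set-equality
between the enumerator and the transcribed catalog, and tests exactly that.

One transcription conflict is preserved deliberately: the tabulated catalog
and the in-text worked example disagree about which id the
compound–similar–compound–binds–protein–similar–protein shape carries (the
table calls it C6 and assigns C15 to binds·causes·caused-by). The packaged
config follows the table; the provenance note in the YAML records the
discrepancy.

## Features

For each catalog meta-path, `extract_features()` computes the commuting
matrix **once** and reads per-pair values for the requested measures:

* `PC` — the raw walk count;
* `RW` — the row-normalized count `PC[i,j]/PC[i,·]`, the probability mass
  of reaching protein *j* from compound *i* along that meta-path. Rows that
  sum to zero stay zero (`0/0 → 0`): an isolated compound carries no walk
  mass, and 0 is the only value that keeps RW within [0, 1] and monotone.

Columns are named `<metapath>_<measure>` in catalog × measure order, so the
three standard feature sets have 29 (`I`: similarity-free PC), 51 (`II`:
all PC) and 102 (`III`: PC + RW) columns. `NPC` and `SRW` (normalized path
count, symmetric random walk) are implemented as optional extensions behind
the `measures` argument but disabled by default — they are not part of the
standard configuration and we make no tuning claims for them.

# Labeled data and leakage control

Bioactivity evidence is thresholded: a pair with a reported value above
10 μM is negatively labeled; a pair flagged active with a value below 1 μM
is positively labeled; anything else is dropped. Pairs labeled both ways by
different records are **dropped, not majority-voted** — no source we model
states a resolution rule, and dropping is the conservative choice; the
count of conflicts is attached to the result.

Before any feature is computed, `leakage_guard()` removes every positively
labeled link from the binding adjacency (globally, not per fold — matching
the protocol the framework reproduces) and *asserts* that no negatively
labeled pair is present as a link; a violation is a data error, not a
warning. A per-pair leave-one-link-out mode would be stricter but changes
the features per row; it can be emulated with `remove_links()` and is
intentionally not the default.

Splitting is random, seeded and **stratified per label**, with the training
share `floor(n_label × 2/3)` under the default 2:1 ratio. Stratification is
a choice: published cohort counts (5,387/26,682 → 3,591 + 17,788 train,
1,796 + 8,894 test) are consistent with either global or per-label
splitting, and per-label floor arithmetic reproduces them exactly, which
the acceptance suite checks. The evolving-network design
(`evolving_split()`) has no random element: pairs tagged `in_network`
train, pairs tagged `post_network` test.

# Classifiers

No random-forest or SVM package is available in the target environment, so
both learners are implemented here, behind the same interface they would
otherwise wrap.

**Random forest** (`rf_fit()`, Rcpp): `ntree` bootstrap CART trees grown to
purity without pruning, best Gini split among `mtry` features drawn without
replacement per node. `ntree` defaults to 500 — the conventional
satisfactory default — and `mtry` is chosen by grid search on the
**out-of-bag error**, the forest's internal unbiased generalization
estimate (no cross-validation needed). Ties in the OOB grid go to the
smaller `mtry`. Predicted probability is the ensemble vote fraction. Two
importance measures are collected during training: mean decrease in
accuracy (per tree, accuracy on its OOB samples before and after permuting
one feature's values among those samples, averaged over trees) and mean
decrease in Gini (split-wise impurity decrease weighted by node share,
accumulated per feature, averaged over trees). All randomness flows through
R's RNG, so `set.seed()`/the `seed` argument make fits reproducible.

**SVM** (`svm_fit()`): soft-margin RBF-kernel SVM solved as its dual QP
with `quadprog` (ridge 1e-8 on the kernel for positive-definiteness).
Features are z-scored with training statistics stored in the model. `C` and
the kernel width λ are tuned by 10-fold cross-validated mean F1 over
logarithmic grids (`C ∈ 2^(−2..6)`, `λ ∈ 2^(−8..2)`) — only optima, not
grids, are conventionally published, so the grids are ours. Probabilities
are Platt-scaled decision values; on separable data the logistic fit
saturates, which is expected (probabilities clip toward 0/1). The dense QP
is O(n³): fine for the package's synthetic-scale use, not for hundreds of
thousands of pairs — a documented limitation.

# Evaluation

* **F1** `= 2TP/(2TP + FP + FN)` at probability threshold 0.5. The
  threshold is a config-exposed decision (`evaluate_model(threshold=)`);
  published work rarely states it, and 0.5 is the neutral default.
* **ROC/PR curves** by threshold sweep with ties grouped. The default AUC
  integration is **trapezoidal**, which is deterministic, dependency-free
  and equals the Mann–Whitney pair statistic with ties counted ½ (tested
  against a brute-force pair count on 1,000 random instances). A natural
  cubic-spline integration mode is available
  (`roc_pr_curves(auc_method = "spline")`) because some published AUCs were
  computed that way; reports carry the mode used.
* **BEDROC** with α = 20 from the closed form
  `RIE · Ra·sinh(α/2)/(cosh(α/2) − cosh(α/2 − α·Ra)) + 1/(1 − e^{α(1−Ra)})`,
  `RIE = Σ e^{−α·r_i/N} / (n·(1/N)(1−e^{−α})/(e^{α/N}−1))`. Ranks are
  1-based after a descending sort with **seeded random tie-breaking** —
  path-count scores are heavily tied at 0, so an unstated tie policy would
  make the metric irreproducible.

# The synthetic world

`generate_hetnet()` emits all 12 edge types at test scale (defaults: 200
compounds, 100 proteins, 4 latent groups). Binding links follow a block
model (`p_in = 0.10` within a matched compound–protein group, `p_out =
0.003` across); similarity links prefer their group (within-group
probability 0.35 for compounds, 0.15 for proteins, cross-group scaled by
`1 − coherence` with coherence 0.95); annotations are drawn with the same
group preference (0.25/0.02). A 0.3 fraction of true binding links is held
out as labeled positives and pre-removed from the emitted network —
mirroring leakage control — and an equal number of never-linked cross-group
pairs become negatives.

The defaults are a deliberate statement of the planted signal, chosen once:
binding is sparse (as real compound–target matrices are), and compound
similarity is dense within analog-series-like groups, making the
**compound-similarity link the dominant planted channel**. With dense
binding instead, shared-target paths (binds·bound-by·binds) would dominate
and similarity would be redundant — a world in which enriching the network
with similarity links could not be shown to matter.

**What a green end-to-end test establishes.** That the pipeline recovers a
strong planted block signal (AUCROC ≥ 0.85 with feature set III), that
similarity-bearing features are where the forest finds the signal, that
adding similarity meta-paths does not hurt (II ≥ I), and that a null world
yields chance AUC. It does **not** establish real-data performance: the
generator has no chemistry (no fingerprints or Tanimoto structure), no
protein families, no degree heavy-tails, and its annotation edges are
conditionally independent given groups — none of which is true of curated
bio-databases.

**The null world.** The stated null is `p_in = p_out`. In a block model
with group-coherent similarity *and* annotation edges, negatives sampled
only from cross-group pairs would still differ from positives through
binding-free annotation paths (compound–treats–disease–caused-by–protein),
i.e. the "null" would carry residual signal. The generator therefore treats
`p_in == p_out` as "no planted signal anywhere": every edge probability
collapses to its group-agnostic average and negatives are sampled from all
never-linked pairs. The null acceptance check uses a larger labeled sample
(base density 0.08, holdout 0.5) purely to shrink the AUC measurement noise
well inside the ±0.05 band.

**Importance criterion.** In any block-model world the short similarity
path compound–similar–compound–binds–protein and its length-4 extensions
(appending protein-side loops, or prepending binds·bound-by) are strongly
correlated, and a random forest splits permutation-importance credit among
correlated features essentially arbitrarily. Requiring the length-2 path
itself to top the ranking would therefore be brittle; the meaningful,
falsifiable statement — and the one the acceptance suite asserts — is that
**both top-2 MDA features traverse the planted compound-similarity link**.
In a co-binding-dominant world this fails (the top features become
similarity-free shared-target paths), so the check genuinely discriminates
the planted channel. This mirrors the qualitative finding the framework is
known for: the most important meta-paths contain similarity neighboring
links.

# Numerical and degenerate-input choices

* `RW`: `0/0 → 0`; rows sum to 1 or 0, tested as a property.
* F1 with `2TP + FP + FN = 0` is defined as 0 with a warning.
* BEDROC requires both actives and inactives; degenerate inputs error.
* Stratified splits error when a label class is absent; floor rounding on
  the training share.
* RF OOB-grid ties → smallest `mtry`; node splits need a strict Gini
  decrease (> 1e-12), so constant features are never split on.
* SVM kernel ridge 1e-8; support vectors at `α > 1e-6`; the intercept
  averages over margin vectors, falling back to all support vectors.
* Seeds: one master seed per experiment; stages derive sub-seeds through a
  fixed integer map (`derive_seed`), so any stage can be regenerated
  independently. Derived seeds stay below 2^31.

# Known limitations

* The SVM's dense QP and kernel matrix limit it to a few thousand training
  pairs; the random forest handles larger tables but holds features densely
  in memory.
* Features for the full unobserved-pair space are never materialized;
  extraction is lazy over requested pair lists by design.
* The importance-stability experiment at its reference scale (1,000
  replicate forests of 500 trees) takes tens of minutes on one CPU; tests
  exercise it at reduced scale and the function exposes `ntree`/`n_models`
  for exactly that reason.
* Real-data ingestion is limited to typed edge-list TSVs; RDF/SPARQL
  tooling is out of scope.
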
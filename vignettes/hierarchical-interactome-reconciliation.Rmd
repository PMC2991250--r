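---
title: "Hierarchically consistent prediction of multiple interaction types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchically consistent prediction of multiple interaction types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoweave)
```

## The problem

Genes interact in many qualitatively different ways — stable physical
association, transient covalent modification such as phosphorylation,
transcriptional regulation, membership in the same metabolic pathway,
synthetic lethality. These types are not independent labels: they form a
hierarchy in which the more specific type implies the more general one
(a phosphorylation *is* a physical interaction *is* a functional
relationship). `ontoweave` predicts all types simultaneously for every
gene pair and forces the predictions to respect that hierarchy, so that a
pair never receives, say, a confident phosphorylation call together with a
rejection of physical interaction.

The system has three layers:

1. **Per-type discriminative scoring.** For each interaction type, a
   bagged ensemble of linear soft-margin classifiers is trained on labeled
   gene pairs described by heterogeneous pairwise features. The ensemble's
   mean decision value is a continuous, unconstrained score.
2. **Bayesian reconciliation.** The per-type scores are discretized and
   treated as noisy observations `Y_t` of latent binary labels `X_t`, one
   per interaction type. A Bayesian network whose structure mirrors the
   type hierarchy (a "decorated tree") couples the labels, and exact
   inference yields marginal posteriors `P(X_t = 1 | all scores)` that are
   hierarchy-consistent by construction.
3. **Network analysis.** Posterior edge weights are binarized into
   per-type interactomes, which are then compared through degree
   statistics, hub overlap, graphlet degree distributions and directed
   3-node motif enrichment.

## The ontology and its gold standard

An `interaction_ontology` is a rooted tree; each term is directed (pairs
are ordered, e.g. kinase → substrate) or undirected. Gold standards are
assembled per term:

* **True-path propagation** (`propagate_positives`): every positive pair
  annotated to a term is copied to all ancestor terms, so positive label
  sets are nested along the hierarchy. An ordered pair contributed to an
  undirected ancestor is canonicalized; an unordered pair is never given a
  direction.
* **Matched negatives** (`sample_negatives`): interactions are sparse, so
  negatives are drawn uniformly from unlabeled pairs, as many as there are
  positives. By default only the term's own positives are excluded from
  the negative pool; sharing negatives across terms is deliberately not
  done, since positive sets differ per term.
* **Direction-flipped negatives** (`make_direction_negatives`): for
  directed terms, each positive (a, b) yields the negative (b, a). A pair
  annotated in both orientations has no incorrect direction; such pairs
  are excluded and reported rather than silently kept.
* **Gene-exclusion splits** (`split_by_gene`): evaluation withholds a
  fraction (default 30%) of *genes*; every pair touching a held-out gene
  is test, everything else is train. This is stricter than holding out
  pairs: the classifier never sees a held-out gene in any pair during
  training. In the end-to-end experiment one gene holdout is drawn
  globally rather than per term, so each pair is consistently train or
  test for the entire Bayesian network.

## Pairwise features

Per-gene data become per-pair features (`features` module):

* expression differences per condition — signed `x_i − x_j` for directed
  terms (antisymmetric under orientation swap), absolute `|x_i − x_j|`
  for undirected ones;
* binary shared-annotation indicators (colocalization compartments,
  protein families): 1 when the two genes' category sets intersect;
* Euclidean distance between per-gene binding-site profiles;
* precomputed alignment E-values, entered as `−log10(max(E, floor))`
  because E-values span many decades and margin classifiers need
  comparable scales (the floor, default 1e−200, caps the dynamic range).

Missing expression values are imputed by gene-wise k-nearest neighbours
(`knn_impute`, k = 10 by default), computed within each dataset of origin;
genes missing more than 30% of their conditions are removed. Neighbour
distances are Euclidean over mutually observed conditions, normalized per
shared condition so genes with different missingness patterns compare
fairly. Observed entries are never altered.

`assemble_features` concatenates feature tables and drops whole source
tags that are too closely related to the predicted type (e.g.
binding-site profiles when predicting regulatory relationships), and all
columns are standardized to zero mean / unit variance on the training
pairs — the classifiers are margin-based, so feature scales matter.

## Base learners

Each term's classifier is a bagged ensemble (default 10 members) of
linear C-classification machines with the error parameter C = 20 — the
libsvm `cost` parameter, the same convention as the C in the standard
soft-margin objective. Each member trains on a stratified bootstrap:
positives resampled with replacement to the positive count, negatives to
the negative count, so no member ever sees a single class. Full-size
resamples are the standard bagging choice. The bagged score is the
arithmetic mean of member decision values, oriented so positives score
high.

## The decorated-tree Bayesian network

Each term contributes a latent binary node `X_t` and an observed evidence
node `Y_t` (the discretized bagged score). The conditional structure
follows the hierarchy with arrows from child terms to their parents:
`P(X_t | children)` is constrained to 1 whenever any child is on, and to
a learned probability `q_t` when all children are off. Because the
network's arrows point from children to parents, the *leaves* of the
ontology are the root nodes of the Bayesian network; their `q_t` is the
vacuous-condition case — the term's smoothed marginal positive frequency
in training labels — and serves as the prior.

### Parameters

* **Discretization** (`fit_discretizer`): scores are clipped to five
  standard deviations either side of the training-score mean and cut into
  `n_bins` equal-width half-open bins; the default `n_bins = 10` gives
  one bin per standard-deviation unit, keeping each observation CPT at
  `10 × 2` entries. Out-of-range scores land in the end bins; zero score
  variance degrades to a single bin with a warning.
* **Observation CPTs** (`learn_observation_cpt`): maximum likelihood with
  Laplace smoothing, `P(Y=b|X=x) = (count + α)/(total + α·n_bins)`,
  α = 1 everywhere. Smoothing guarantees strictly positive likelihoods,
  so the downstream message passing never divides by zero.
* **Structural CPTs** (`learn_structural_cpts`): `q_t` is the smoothed
  fraction of the term's labeled training pairs positive at the term
  among those positive at no child, `q = (k + α)/(n + 2α)`. Labels must
  be hierarchy-consistent (a pair positive at a child but negative at the
  parent is a hard error, reported with examples).
* **Calibration scores.** In the end-to-end pipeline the discretizer and
  observation CPTs are fitted on *out-of-bag* bagged scores
  (`predict_scores_oob`): each training pair is scored only by ensemble
  members whose bootstrap resample did not contain it. In-bag decision
  values of a C = 20 ensemble sit beyond the margin almost by
  construction and misrepresent the score distribution of new pairs,
  which makes `P(Y|X)` overconfident; out-of-bag scoring is the standard
  calibration device for bagged ensembles and restores agreement between
  the training-time and test-time evidence distributions.

### Exact inference

`infer_posteriors` runs sum-product message passing over the tree. The
constrained CPT factorizes —
`P(X_t = 0 | children) = (1 − q_t) · ∏_c 1[X_c = 0]` — so the upward
message at a term costs O(#children) regardless of fan-in, and no fan-in
cap or dense child-configuration table is needed. Messages are
normalized per pair for numerical stability; with smoothed CPTs all
message components are strictly positive, so the leave-one-out divisions
in the downward pass are well defined. Posteriors provably satisfy
`P(parent) ≥ P(child)` because the joint distribution places zero mass on
(parent off, child on); the test suite asserts this on every pair and
edge rather than assuming it, and checks exact agreement (to 1e−9)
with brute-force enumeration over all `2^n` latent assignments on
hundreds of random trees.

Marginal posteriors are the primary output, since ranked-edge evaluation
(ROC) needs continuous per-term scores. A joint maximum-a-posteriori
assignment (`map_assignment`, max-product with backtracking) is provided
as a secondary mode for users who want a single consistent label set per
pair. A missing score can either be treated as unobserved evidence
(marginalized, the default) or raised as an error.

### Mixed directedness

The inference instance is an ordered pair. Undirected terms receive
orientation-invariant features by construction, so their evidence — and
hence their posteriors — are identical for both orientations; directed
terms are scored per orientation. A directed child under an undirected
parent is supported: the parent simply receives the same evidence for
both orientations while the child discriminates between them.

## Evaluation

`roc_auc` implements the Mann–Whitney rank statistic with midrank ties,
which equals the trapezoidal area under the tie-aware ROC curve.
`directionality_auc` asks how often a directed interaction's correct
orientation outranks its flip — positives are the annotated orientations,
negatives the same pairs reversed. `improvement_report` tabulates
per-term reconciled-minus-isolated AUC with a macro-averaged summary
(terms are averaged, not pairs pooled, so large terms do not dominate).

## Topology analysis

* `binarize` keeps edges strictly above `mean + k·sd` of the edge
  weights; k = 5 is the default and k = 3 the common alternative, and the
  retained fraction is always recorded so the "top ~1% of edges" regime
  is checkable on any input.
* `degree_stats` reports degree histograms (in/out separately for
  directed networks) and the log–log least-squares slope as a scale-free
  diagnostic; a regular graph has no defined slope and reports `NA`.
* `hub_overlap` computes `P[g ∈ top-5%(N1) | g ∈ top-5%(N2)]` over a
  shared node universe, with directed networks contributing separate
  in-degree and out-degree variants, ties broken by gene id for
  determinism, and an average-linkage clustering order on
  `1 − overlap`.
* `orbit_counts` counts, per node, incidences in the 73 automorphism
  orbits of the 30 connected 2–5-node graphlets by exact ESU enumeration
  of connected induced subgraphs (C++ backend). The catalog of graphlets
  and orbits is generated deterministically — graphlets ordered by size,
  edge count and canonical adjacency code; orbits within a graphlet by
  degree and marked-vertex canonical code — which reproduces the
  conventional small numbering (orbit 0 = edge end = degree, orbits 1/2 =
  path ends/middle, orbit 3 = triangle). Enumeration is refused above
  5,000 nodes / 50,000 edges by default; genome-scale graphs should be
  thresholded harder or sampled first.
* `gdd_agreement` compares two networks' graphlet degree distributions:
  per orbit, the distribution of per-node counts is scaled by 1/k,
  normalized, and compared by Euclidean distance scaled into [0, 1];
  agreements are averaged arithmetically over the 73 orbits (geometric
  averaging is available). An orbit empty in both networks agrees
  perfectly; empty in exactly one, it is compared against the zero
  distribution.
* `triad_census` / `motif_enrichment` count the 13 connected directed
  triad classes exhaustively and compare against degree-preserving
  double-edge-swap null networks (defaults: 500 nulls, 10 accepted swaps
  per edge), reporting per-class z-scores and empirical p-values; a class
  with zero null variance is flagged rather than given a fake z. A
  FANMOD-style sampled census (`triad_census_sampled`, per-level
  retention probabilities 0.6/0.5/0.4) is available for graphs too large
  to enumerate. Exhaustive search is exact and entirely feasible at the
  scales this package targets, so it is the default. Directed 4-node
  motifs are out of scope.

## The synthetic benchmark

No public compendium ships with the package; `synth_config` defines a
fully synthetic study instead, and every default is a fixed study
condition rather than a tunable knob:

* **Shape:** a 2-level, 8-term ontology — a root ("functional
  relationship" analogue) with 7 leaf types, 40% of leaves directed
  (mirroring the 12-of-30 directed share typical of curated interaction
  hierarchies); 500 genes.
* **Labels:** each leaf marks each gene pair positive independently with
  probability 0.005 — interactions are sparse, and this yields hundreds
  of positives per leaf and a few thousand at the root after propagation;
  negatives are matched 1:1.
* **Signal:** each term owns 4 informative feature columns on which its
  positives are shifted by δ; δ cycles through {0.5, 1, 2} across terms
  so that weak and strong types coexist and borrowing strength across the
  hierarchy is observable. Directed terms' shifts are antisymmetric
  (+δ for the correct orientation, −δ flipped); 20 shared pure-noise
  columns and unit noise complete the design. Feature values are drawn
  once per canonical pair so both orientations are mutually consistent.
  Each term's table contains its own informative columns plus the shared
  noise columns — sibling terms' informative columns are excluded so
  per-term evidence is independent and any reconciliation gain is
  attributable to the hierarchy, not to shared columns.

What the generator does *not* emulate: correlated expression structure,
heavy-tailed feature distributions, annotation bias, and the sheer scale
of a real compendium (thousands of conditions, millions of labels).
Passing tests on this benchmark demonstrate that the machinery is correct
and that hierarchy coupling behaves as designed — not that any particular
accuracy will be attained on real data.

## Problem sizes and what the experiments show

`run_reconciliation_experiment` (8 terms × 500 genes, 30% gene holdout,
10 members, C = 20, 10 bins, α = 1) trains ~80 classifiers and
reconciles roughly ten thousand held-out pairs in a couple of minutes on
one core. Across seeds, reconciled posteriors improve the macro-averaged
held-out AUC over the isolated classifiers, with the largest gains at
weak-signal terms (the root and δ = 0.5 leaves) — the same qualitative
pattern as hierarchical-classification systems report on real compendia —
while near-saturated terms (δ = 2, AUC ≈ 0.99) can give up a little
within-bin resolution to discretization. `run_directionality_experiment`
(one directed term, 150 genes, 5% positive rate) recovers orientation
essentially perfectly at δ = 2 and sits at exactly 0.5 under δ = 0,
because with no antisymmetric signal the scorer is orientation-symmetric
by construction.

## Numerical and degenerate-input conventions

* Ties in hub selection and neighbour selection break by id for
  determinism; every stochastic step takes an explicit seed and restores
  the caller's RNG state.
* Zero score variance → single-bin discretizer (warning); zero weight
  variance → empty binary network (warning); single-class label sets are
  errors, not silent degeneracies.
* Bootstrap resamples are stratified, so degenerate one-class members
  cannot occur.
* The pair container forbids self-pairs globally; undirected pairs are
  stored in canonical (lexicographic) order everywhere.
* DAG-shaped ontologies are rejected outright rather than reduced to a
  tree.

## Known limitations

* Inference is exact only because ontologies are trees; DAG ontologies
  (shared subterms) are out of scope.
* The observation model assumes one score per (pair, term); multiple
  heterogeneous classifiers per term would need a product of evidence
  nodes.
* Orbit counting is exhaustive and intended for thresholded interactomes
  (≲ 50k edges), not raw weighted graphs.
* The linear-kernel base learner is a pluggable default, not a claim that
  linear margins are optimal for every feature family.
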
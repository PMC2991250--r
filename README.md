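# ontoweave

Genes interact in many qualitatively different ways — stable physical
binding, phosphorylation and other covalent modifications, transcriptional
regulation, shared metabolic pathways, synthetic lethality — and these
types are hierarchically related: the more specific type implies the more
general one. `ontoweave` predicts **all** interaction types for every gene
pair **simultaneously** and guarantees that the predictions respect the
hierarchy. It is aimed at computational biologists who have an interaction
ontology, per-type gold standards and heterogeneous pairwise genomic
features, and want per-type weighted interactomes that never contradict
each other.

## The model

For each interaction type *t* in a rooted ontology, a bagged ensemble of
linear soft-margin classifiers (10 members, C = 20, stratified bootstrap)
produces a continuous score for each gene pair. The scores are then
reconciled by a Bayesian network that mirrors the ontology — a *decorated
tree*:

* each type contributes a latent label `X_t ∈ {0,1}` and an observed node
  `Y_t`, the bagged score discretized into 10 equal-width bins spanning
  the training mean ± 5 standard deviations;
* `P(Y_t | X_t)` is learned by maximum likelihood with Laplace smoothing
  (α = 1) from out-of-bag training scores;
* the hierarchy is enforced structurally:
  `P(X_t = 1 | any child on) = 1`, and
  `P(X_t = 1 | all children off) = q_t` is the smoothed conditional
  frequency counted from the propagated training labels (for leaf terms,
  whose condition is vacuous, `q_t` is the term's prior).

Exact sum-product message passing yields, per pair, the marginal
posteriors `P(X_t = 1 | all Y)`; these provably satisfy
`posterior(parent) ≥ posterior(child)` on every edge. Gold standards are
assembled with true-path propagation, equal-size uniform negatives,
direction-flipped negatives for directed types, and evaluation splits
that exclude ~30% of *genes* from training. Evaluation is midrank
ROC/AUC, including a directionality AUC (does the correct orientation of
a directed interaction outrank its flip?). Binarized interactomes are
compared by degree statistics, top-5% hub overlap, 73-orbit graphlet
degree distributions (GDD agreement) and 3-node motif enrichment against
degree-preserving edge-swap nulls.

A fully seeded synthetic generator (ontology, hierarchy-consistent
planted labels, per-term Gaussian feature signal with antisymmetric
orientation signal for directed types) makes the whole pipeline testable
without any external data.

## Worked example

Run the end-to-end synthetic experiment — generate an 8-term ontology
(3 directed leaves) over 120 genes, train per-term ensembles, reconcile,
and compare isolated versus reconciled held-out AUC:

```r
library(ontoweave)
cfg <- synth_config(n_genes = 120, pos_rate = 0.02)
ex  <- run_reconciliation_experiment(cfg, seed = 7)
print(ex$ontology)
#> interaction ontology: 8 terms, root 'root', 3 directed
ex$report
#>   term auc_base auc_reconciled  delta
#> 1 root    0.751          0.776  0.025
#> 2   t1    0.889          0.890  0.001
#> 3   t2    0.997          0.989 -0.008
#> 4   t3    0.691          0.725  0.034
#> 5   t4    0.938          0.920 -0.018
#> 6   t5    0.999          0.999 -0.001
#> 7   t6    0.670          0.756  0.087
#> 8   t7    0.865          0.840 -0.025
attr(ex$report, "summary")[["mean"]]
#> +0.0118
```

Reconciliation lifts the weak-signal types the most (here `t6`:
0.670 → 0.756; the root gains 0.025) while near-saturated types give up a
little within-bin resolution to discretization — the macro-average
improves. The posteriors are hierarchy-consistent for every one of the
1,453 held-out pairs:

```r
post <- ex$posteriors$posterior
all(post[, "root"] >= post[, "t3"] - 1e-9)
#> TRUE
```

Motif analysis of a directed network with planted feed-forward loops
(A→B, A→C, B→C) against 100 degree-preserving edge-swap nulls:

```r
net <- plant_ffl_network(seed = 1)   # 60 nodes, 189 directed edges
enr <- motif_enrichment(net, n_random = 100, seed = 2)
enr[enr$class %in% c("021C", "030T", "030C"), ]
#>  class real null_mean null_sd     z p_emp
#>   021C  479    467.22   27.80  0.42  0.36
#>   030T   57     34.78    5.82  3.82  0.00
#>   030C    6      9.09    2.95 -1.05  0.85
```

The planted motif class (`030T`, the feed-forward loop) stands out at
z ≈ 3.8 while chains and cycles stay at their null level.

See `vignettes/hierarchical-interactome-reconciliation.Rmd` for the full
account of the model, its parameters and the synthetic study design, and
`inst/cli/ontoweave.R` for a command-line wrapper
(`simulate` / `pipeline` / `topology`).

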
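#' End-to-end synthetic reconciliation experiment
#'
#' Runs the full system on one synthetic benchmark draw: generate ontology,
#' planted labels and features; hold out a shared fraction of genes; train
#' per-term bagged margin classifiers on the training pairs; fit the
#' discretizers, observation CPTs and structural CPTs on training data;
#' infer hierarchically consistent posteriors for all held-out pairs; and
#' evaluate isolated-classifier versus reconciled AUC per term.
#'
#' The gene holdout is drawn once and shared across terms so that each
#' pair is consistently train or test for the whole Bayesian network.
#'
#' @param cfg a [synth_config()].
#' @param seed master seed for the run (defaults to `cfg$seed`); every
#'   stochastic step derives its own seed from it.
#' @param holdout_fraction fraction of genes excluded from training
#'   (default 0.3).
#' @param n_members bagging ensemble size (default 10).
#' @param cost margin-classifier error parameter (default 20).
#' @param n_bins discretization bins (default 10).
#' @param pseudocount Laplace pseudocount (default 1).
#' @return list with the generated `ontology`, `labels`, `splits`,
#'   `classifiers`, fitted `model`, held-out pair `pairs`, score matrix
#'   `scores`, `posteriors`, per-term `roc_base` / `roc_reconciled` and
#'   the improvement `report`.
#' @export
run_reconciliation_experiment <- function(cfg = synth_config(),
                                          seed = cfg$seed,
                                          holdout_fraction = 0.3,
                                          n_members = 10, cost = 20,
                                          n_bins = 10, pseudocount = 1) {
  o <- make_ontology(cfg, seed = seed)
  labels <- plant_labels(o, cfg, seed = seed + 1L)
  genes <- synth_genes(cfg)
  holdout <- with_seed(seed + 2L,
                       sample(genes, ceiling(holdout_fraction * length(genes))))
  splits <- lapply(labels, split_by_gene, holdout_genes = holdout)
  fm <- make_features(labels, cfg, seed = seed + 3L)

  terms <- o$terms$id
  classifiers <- list()
  standardizers <- list()
  discretizers <- list()
  obs_cpts <- list()
  train_scores <- list()
  for (i in seq_along(terms)) {
    t <- terms[i]
    tr <- splits[[t]]$train
    tr_pairs <- rbind(tr$positives, tr$negatives)
    ft <- synth_features(fm, tr_pairs, t)
    std <- fit_standardizer(ft)
    ft <- apply_standardizer(ft, std)
    clf <- train_bagged(ft, tr, n_members = n_members, cost = cost,
                        seed = seed + 10L + i)
    # calibrate the evidence model on out-of-bag scores: in-bag decision
    # values of a soft-margin ensemble overstate the separation seen on
    # held-out pairs
    sc <- predict_scores_oob(clf, ft)
    classifiers[[t]] <- clf
    standardizers[[t]] <- std
    train_scores[[t]] <- sc
    discretizers[[t]] <- fit_discretizer(sc, n_bins = n_bins)
    obs_cpts[[t]] <- learn_observation_cpt(sc, tr, discretizers[[t]],
                                           pseudocount = pseudocount)
  }
  struct_cpts <- learn_structural_cpts(
    o, lapply(splits, `[[`, "train"), pseudocount = pseudocount)
  model <- hierarchical_model(o, discretizers, obs_cpts, struct_cpts)

  # union of all held-out labeled pairs, as stored (ordered for directed
  # terms, canonical otherwise)
  test_pairs <- dedup_pairs(do.call(rbind, lapply(splits, function(s) {
    rbind(s$test$positives, s$test$negatives)
  })))
  rownames(test_pairs) <- NULL
  scores <- matrix(NA_real_, nrow(test_pairs), length(terms),
                   dimnames = list(NULL, terms))
  for (t in terms) {
    ft <- apply_standardizer(synth_features(fm, test_pairs, t),
                             standardizers[[t]])
    scores[, t] <- predict_scores(classifiers[[t]], ft)$scores
  }
  posteriors <- infer_posteriors(model, scores, pairs = test_pairs)

  tkeys <- pair_key(test_pairs$a, test_pairs$b)
  roc_base <- list()
  roc_rec <- list()
  for (t in terms) {
    te <- splits[[t]]$test
    idx <- match(c(pair_key(te$positives$a, te$positives$b),
                   pair_key(te$negatives$a, te$negatives$b)), tkeys)
    lab <- rep(c(1, -1), c(nrow(te$positives), nrow(te$negatives)))
    roc_base[[t]] <- roc_auc(scores[idx, t], lab, term = t)
    roc_rec[[t]] <- roc_auc(posteriors$posterior[idx, t], lab, term = t)
  }
  report <- improvement_report(roc_base, roc_rec)

  list(ontology = o, labels = labels, splits = splits, feature_model = fm,
       classifiers = classifiers, standardizers = standardizers,
       train_scores = train_scores, model = model, pairs = test_pairs,
       scores = scores, posteriors = posteriors, roc_base = roc_base,
       roc_reconciled = roc_rec, report = report)
}

#' Directionality-recovery experiment on a single directed term
#'
#' Trains a bagged classifier for one directed interaction type with
#' antisymmetric planted signal `delta`, scores both orientations of the
#' held-out positives, and measures the directionality AUC (frequency with
#' which the correct orientation outranks the flipped one). With
#' `delta = 0` the scorer is orientation-symmetric and the AUC sits at
#' 0.5.
#'
#' @param delta antisymmetric signal strength on the informative columns.
#' @param n_genes,pos_rate size of the synthetic draw (defaults 150 genes,
#'   5% positive pairs).
#' @param seed master seed.
#' @param n_members,cost classifier settings as in
#'   [run_reconciliation_experiment()].
#' @return list with the directionality `roc` (a `roc_result`), the
#'   held-out positive count and the trained classifier.
#' @export
run_directionality_experiment <- function(delta, n_genes = 150,
                                          pos_rate = 0.05, seed = 1,
                                          n_members = 10, cost = 20) {
  cfg <- synth_config(n_genes = n_genes, depth = 1, branching = 1,
                      frac_directed = 1, pos_rate = pos_rate,
                      delta = delta, seed = seed)
  o <- make_ontology(cfg, seed = seed)
  leaf <- leaf_terms(o)[1]
  labels <- plant_labels(o, cfg, seed = seed + 1L)
  split <- split_by_gene(labels[[leaf]], holdout_fraction = 0.3,
                         seed = seed + 2L)
  fm <- make_features(labels, cfg, seed = seed + 3L)
  tr <- split$train
  ft_tr <- synth_features(fm, rbind(tr$positives, tr$negatives), leaf)
  std <- fit_standardizer(ft_tr)
  clf <- train_bagged(apply_standardizer(ft_tr, std), tr,
                      n_members = n_members, cost = cost,
                      seed = seed + 4L)
  te_pos <- split$test$positives
  both <- dedup_pairs(rbind(te_pos, flip_pairs(te_pos)))
  sc <- predict_scores(clf, apply_standardizer(
    synth_features(fm, both, leaf), std))
  roc <- directionality_auc(sc, te_pos)
  list(roc = roc, n_test_positives = nrow(te_pos), classifier = clf,
       term = leaf)
}
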
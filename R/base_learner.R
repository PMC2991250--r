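#' Bagged linear maximum-margin classifiers
#'
#' Each interaction type gets an ensemble of linear soft-margin classifiers
#' (libsvm C-classification, linear kernel, error parameter C = 20 by
#' default), each member trained on a stratified bootstrap resample of the
#' term's labeled pairs (with replacement, resample size = class size, both
#' classes guaranteed present). The bagged score of a pair is the
#' arithmetic mean of the members' decision values; these continuous scores
#' are the noisy observations fed to the Bayesian reconciliation.
#'
#' @param features a `feature_table` covering all labeled pairs.
#' @param labels a `pair_label_set` with at least one positive and one
#'   negative pair.
#' @param n_members ensemble size (default 10).
#' @param cost soft-margin error parameter C of the underlying solver
#'   (default 20).
#' @param seed integer; fixes the bootstrap draws.
#' @return object of class `bagged_classifier`: term id, per-member weight
#'   vectors and offsets, feature-name manifest, `n_members`, `cost`,
#'   per-member seeds.
#' @export
train_bagged <- function(features, labels, n_members = 10, cost = 20,
                         seed = 1) {
  stopifnot(inherits(features, "feature_table"),
            inherits(labels, "pair_label_set"), n_members >= 1)
  n_pos <- nrow(labels$positives)
  n_neg <- nrow(labels$negatives)
  if (n_pos == 0L || n_neg == 0L) {
    stop(sprintf("term '%s': both classes required for training (%d+, %d-)",
                 labels$term, n_pos, n_neg))
  }
  fkeys <- pair_key(features$pairs$a, features$pairs$b)
  locate <- function(p, what) {
    idx <- match(pair_key(p$a, p$b), fkeys)
    if (anyNA(idx)) {
      miss <- p[is.na(idx), , drop = FALSE]
      stop(sprintf("term '%s': %d %s pair(s) missing from feature table (e.g. %s-%s)",
                   labels$term, sum(is.na(idx)), what, miss$a[1], miss$b[1]))
    }
    idx
  }
  ip <- locate(labels$positives, "positive")
  ineg <- locate(labels$negatives, "negative")
  X <- features$values
  member_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_members))
  members <- lapply(member_seeds, function(s) {
    idx <- with_seed(s, c(sample(ip, n_pos, replace = TRUE),
                          sample(ineg, n_neg, replace = TRUE)))
    y <- factor(rep(c("pos", "neg"), c(n_pos, n_neg)),
                levels = c("neg", "pos"))
    m <- fit_linear_margin(X[idx, , drop = FALSE], y, cost)
    m$inbag <- unique(idx)
    m
  })
  structure(list(term = labels$term, members = members,
                 n_members = n_members, cost = cost,
                 feature_names = colnames(X), seeds = member_seeds,
                 labeled_rows = c(ip, ineg)),
            class = "bagged_classifier")
}

# Fit one linear C-classification machine and return (w, b) such that the
# decision value X %*% w + b is positive for class "pos".
fit_linear_margin <- function(X, y, cost) {
  m <- e1071::svm(X, y, type = "C-classification", kernel = "linear",
                  cost = cost, scale = FALSE, fitted = FALSE)
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # libsvm orients the decision function toward the first encountered
  # class; verify against predict() and normalize to "pos"-positive.
  take <- seq_len(min(5L, nrow(X)))
  ref <- drop(attr(stats::predict(m, X[take, , drop = FALSE],
                                  decision.values = TRUE),
                   "decision.values"))
  own <- drop(X[take, , drop = FALSE] %*% w) + b
  if (max(abs(own - ref)) > max(abs(own + ref))) {
    w <- -w
    b <- -b
  }
  first <- strsplit(colnames(attr(stats::predict(
    m, X[1, , drop = FALSE], decision.values = TRUE),
    "decision.values")), "/")[[1]][1]
  if (first != "pos") {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

#' @export
print.bagged_classifier <- function(x, ...) {
  cat(sprintf("bagged classifier '%s': %d linear members, C = %g, %d features\n",
              x$term, x$n_members, x$cost, length(x$feature_names)))
  invisible(x)
}

#' Bagged decision scores
#'
#' @param m a `bagged_classifier`.
#' @param features a `feature_table` whose columns match the training
#'   feature space (names and order).
#' @return a `score_table`: term, pairs and the mean decision value per
#'   pair.
#' @export
predict_scores <- function(m, features) {
  stopifnot(inherits(m, "bagged_classifier"),
            inherits(features, "feature_table"))
  if (!identical(colnames(features$values), m$feature_names)) {
    extra <- setdiff(colnames(features$values), m$feature_names)
    miss <- setdiff(m$feature_names, colnames(features$values))
    stop(sprintf("feature space mismatch for term '%s'%s%s; columns must match in name and order",
                 m$term,
                 if (length(miss)) paste0("; missing: ", paste(utils::head(miss, 5), collapse = ", ")) else "",
                 if (length(extra)) paste0("; unexpected: ", paste(utils::head(extra, 5), collapse = ", ")) else ""))
  }
  per_member <- vapply(m$members, function(mb) {
    drop(features$values %*% mb$w) + mb$b
  }, numeric(nrow(features$values)))
  per_member <- matrix(per_member, nrow = nrow(features$values))
  score_table(m$term, features$pairs, rowMeans(per_member))
}

#' Out-of-bag bagged scores for training pairs
#'
#' For calibration steps fitted on training data (score discretization and
#' observation CPTs), in-bag decision values of a soft-margin ensemble are
#' systematically pushed beyond the margin and misrepresent the score
#' distribution seen on new pairs. The out-of-bag score of a training pair
#' averages only the members whose bootstrap resample did not contain it;
#' pairs present in every resample fall back to the full bagged mean.
#'
#' @param m a `bagged_classifier`.
#' @param features the training `feature_table` the classifier was fitted
#'   on (same rows).
#' @return a `score_table` of out-of-bag scores.
#' @export
predict_scores_oob <- function(m, features) {
  full <- predict_scores(m, features)
  n <- nrow(features$values)
  per_member <- vapply(m$members, function(mb) {
    drop(features$values %*% mb$w) + mb$b
  }, numeric(n))
  per_member <- matrix(per_member, nrow = n)
  oob <- matrix(TRUE, n, m$n_members)
  for (j in seq_len(m$n_members)) {
    inb <- m$members[[j]]$inbag
    oob[inb[inb <= n], j] <- FALSE
  }
  k <- rowSums(oob)
  sc <- ifelse(k > 0, rowSums(per_member * oob) / pmax(k, 1), full$scores)
  score_table(m$term, features$pairs, sc)
}

#' Score tables
#'
#' Continuous bagged classifier outputs for one term, aligned with a pair
#' sequence.
#'
#' @param term term id.
#' @param pairs data.frame of gene pairs.
#' @param scores numeric vector of finite decision values.
#' @return object of class `score_table`.
#' @export
score_table <- function(term, pairs, scores) {
  stopifnot(length(scores) == nrow(pairs), all(is.finite(scores)))
  structure(list(term = term, pairs = new_pairs(pairs$a, pairs$b),
                 scores = as.numeric(scores)),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score table '%s': %d pairs, scores in [%.3g, %.3g]\n",
              x$term, length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}
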
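#' ROC analysis of predicted interactomes
#'
#' AUC is computed by the Mann-Whitney rank statistic with midrank tie
#' handling (ties count 1/2), which equals the trapezoidal area under the
#' tie-aware ROC curve.
#'
#' @param scores numeric vector of prediction scores for labeled pairs.
#' @param labels vector of +1/-1 (or logical) labels, one per score.
#' @param term optional term id carried through for reporting.
#' @return object of class `roc_result`: `auc`, the ROC `curve`
#'   (data.frame of `fpr`, `tpr`, starting at (0,0) and ending at (1,1)),
#'   and `n_pos` / `n_neg`.
#' @export
roc_auc <- function(scores, labels, term = NA_character_) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (is.logical(labels)) labels <- ifelse(labels, 1, -1)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1/-1 (or logical)")
  pos <- labels == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes are required to compute an ROC curve")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # tie-aware curve: one point per distinct score, descending
  ord <- order(-scores)
  s <- scores[ord]
  p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(!p)[!duplicated(grp, fromLast = TRUE)]
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(term = term, auc = auc, curve = curve,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC%s: AUC = %.4f (%d positives, %d negatives)\n",
              if (is.na(x$term)) "" else paste0(" '", x$term, "'"),
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Directionality AUC for a directed term
#'
#' Measures how often an interaction's correct direction outranks its
#' incorrect direction: positives are the scores of the annotated
#' orientations, negatives the scores of the same pairs flipped.
#' Bidirectional positives (both orientations annotated) have no incorrect
#' direction and are excluded, reported via the `excluded` attribute.
#'
#' @param scores a `score_table` or `posterior_table` that contains both
#'   orientations of every positive pair; for a `posterior_table`, `term`
#'   selects the column.
#' @param positives data.frame of annotated ordered pairs.
#' @param term term id (required for a `posterior_table`).
#' @return a `roc_result` (with attribute `excluded`).
#' @export
directionality_auc <- function(scores, positives, term = NULL) {
  if (inherits(scores, "score_table")) {
    pairs <- scores$pairs
    vals <- scores$scores
    term <- term %||% scores$term
  } else if (inherits(scores, "posterior_table")) {
    if (is.null(term)) stop("`term` is required with a posterior table")
    pairs <- scores$pairs
    vals <- scores$posterior[, term]
  } else {
    stop("`scores` must be a score_table or posterior_table")
  }
  pos <- as_pairs(positives, directed = TRUE)
  keys <- pair_key(pos$a, pos$b)
  bidir <- pair_key(pos$b, pos$a) %in% keys
  pos_use <- pos[!bidir, , drop = FALSE]
  skeys <- pair_key(pairs$a, pairs$b)
  i_fwd <- match(pair_key(pos_use$a, pos_use$b), skeys)
  i_rev <- match(pair_key(pos_use$b, pos_use$a), skeys)
  bad <- is.na(i_fwd) | is.na(i_rev)
  if (any(bad)) {
    ex <- pos_use[bad, , drop = FALSE]
    stop(sprintf(
      "%d positive pair(s) lack a score for one orientation (e.g. %s-%s)",
      sum(bad), ex$a[1], ex$b[1]))
  }
  res <- roc_auc(c(vals[i_fwd], vals[i_rev]),
                 rep(c(1, -1), each = nrow(pos_use)), term = term)
  attr(res, "excluded") <- pos[bidir, , drop = FALSE]
  res
}

#' Base-versus-reconciled improvement report
#'
#' Per-term difference between reconciled and isolated-classifier AUCs,
#' with mean/min/max summary (macro-averaged over terms).
#'
#' @param base named list of `roc_result`s for the isolated classifiers.
#' @param reconciled named list of `roc_result`s for the reconciled
#'   posteriors, over the same terms and test pairs.
#' @return data.frame (`term`, `auc_base`, `auc_reconciled`, `delta`) with
#'   attribute `summary` = c(mean, min, max) of the deltas.
#' @export
improvement_report <- function(base, reconciled) {
  if (!setequal(names(base), names(reconciled))) {
    stop("base and reconciled results cover different terms")
  }
  terms <- names(base)
  for (t in terms) {
    if (base[[t]]$n_pos != reconciled[[t]]$n_pos ||
        base[[t]]$n_neg != reconciled[[t]]$n_neg) {
      stop(sprintf("term '%s': base and reconciled use different test sets", t))
    }
  }
  d <- data.frame(
    term = terms,
    auc_base = vapply(base[terms], function(r) r$auc, 0),
    auc_reconciled = vapply(reconciled[terms], function(r) r$auc, 0),
    stringsAsFactors = FALSE
  )
  d$delta <- d$auc_reconciled - d$auc_base
  attr(d, "summary") <- c(mean = mean(d$delta), min = min(d$delta),
                          max = max(d$delta))
  rownames(d) <- NULL
  d
}
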
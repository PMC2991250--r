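#' Score discretization for Bayesian reconciliation
#'
#' Bagged classifier scores enter the Bayesian network as discrete
#' evidence. A scheme clips scores to five standard deviations either side
#' of the training-score mean and cuts that range into `n_bins` equal-width
#' half-open bins (default 10, one per standard-deviation unit);
#' out-of-range scores fall into the end bins.
#'
#' @param scores a `score_table` of training scores, or a numeric vector.
#' @param n_bins number of bins (default 10).
#' @return object of class `discretization_scheme`: term, training `mean`
#'   and `sd`, `n_bins`, and the `n_bins + 1` bin `edges`.
#' @export
fit_discretizer <- function(scores, n_bins = 10) {
  term <- NA_character_
  if (inherits(scores, "score_table")) {
    term <- scores$term
    scores <- scores$scores
  }
  stopifnot(n_bins >= 1, length(scores) >= 1)
  m <- mean(scores)
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) {
    warning("zero score variance; using a single-bin scheme")
    return(structure(list(term = term, mean = m, sd = 0, n_bins = 1L,
                          edges = c(m - 0.5, m + 0.5)),
                     class = "discretization_scheme"))
  }
  edges <- seq(m - 5 * s, m + 5 * s, length.out = n_bins + 1)
  structure(list(term = term, mean = m, sd = s, n_bins = as.integer(n_bins),
                 edges = edges),
            class = "discretization_scheme")
}

#' @rdname fit_discretizer
#' @param d a `discretization_scheme`.
#' @param x numeric scores.
#' @return `discretize()` returns 1-based bin indices in `1..n_bins`; every
#'   real score maps to exactly one bin (bins are `[edge_i, edge_{i+1})`,
#'   scores beyond the clipped range map to the end bins).
#' @export
discretize <- function(d, x) {
  stopifnot(inherits(d, "discretization_scheme"))
  idx <- findInterval(x, d$edges)
  pmin(pmax(idx, 1L), d$n_bins)
}

#' Observation conditional probability tables
#'
#' Maximum-likelihood estimate with Laplace smoothing of P(Y = bin | X),
#' where Y is the discretized bagged score and X the latent binary label:
#' `P(Y=b|X=x) = (count(b,x) + alpha) / (count(x) + alpha * n_bins)`.
#'
#' @param scores a `score_table` of training scores covering every labeled
#'   pair.
#' @param labels the term's training `pair_label_set` (both classes
#'   non-empty).
#' @param d the term's `discretization_scheme`.
#' @param pseudocount Laplace pseudocount alpha (default 1).
#' @return object of class `observation_cpt` with matrix `p` (`n_bins` x 2,
#'   columns `"0"` and `"1"`); each column sums to one and, with
#'   `pseudocount > 0`, every entry is positive.
#' @export
learn_observation_cpt <- function(scores, labels, d, pseudocount = 1) {
  stopifnot(inherits(scores, "score_table"),
            inherits(labels, "pair_label_set"),
            inherits(d, "discretization_scheme"))
  skeys <- pair_key(scores$pairs$a, scores$pairs$b)
  bins_for <- function(p, what) {
    idx <- match(pair_key(p$a, p$b), skeys)
    if (anyNA(idx)) {
      stop(sprintf("term '%s': %d %s training pair(s) have no score",
                   labels$term, sum(is.na(idx)), what))
    }
    discretize(d, scores$scores[idx])
  }
  if (nrow(labels$positives) == 0L || nrow(labels$negatives) == 0L) {
    stop(sprintf("term '%s': a class has zero training pairs", labels$term))
  }
  cpos <- tabulate(bins_for(labels$positives, "positive"), d$n_bins)
  cneg <- tabulate(bins_for(labels$negatives, "negative"), d$n_bins)
  a <- pseudocount
  p <- cbind("0" = (cneg + a) / (sum(cneg) + a * d$n_bins),
             "1" = (cpos + a) / (sum(cpos) + a * d$n_bins))
  structure(list(term = labels$term, p = p, pseudocount = a),
            class = "observation_cpt")
}

#' Structural conditional probability tables
#'
#' The ontology's hierarchy is encoded by constrained CPTs: a term is
#' positive with probability 1 when any of its children is positive, and
#' with a learned probability `q` when all children are negative. `q` is
#' the Laplace-smoothed fraction of the term's labeled training pairs that
#' are positive at the term among those positive at no child. For a leaf
#' the child condition is vacuous, so its `q` is the smoothed marginal
#' positive fraction — the prior of a root node of the Bayesian network
#' (arrows run from child terms to their parents).
#'
#' @param o the modeled `interaction_ontology`.
#' @param train_labels named list, term id -> training `pair_label_set`,
#'   hierarchy-consistent (positives propagated).
#' @param pseudocount Laplace pseudocount alpha (default 1).
#' @return named list of `structural_cpt` objects (fields `term`,
#'   `children`, `q`, `n` = conditioning-set size), one per term of `o`.
#' @export
learn_structural_cpts <- function(o, train_labels, pseudocount = 1) {
  check_term(o, names(train_labels))
  missing <- setdiff(o$terms$id, names(train_labels))
  if (length(missing)) {
    stop("training labels missing for term(s): ",
         paste(missing, collapse = ", "))
  }
  a <- pseudocount
  pos_keys <- lapply(train_labels, function(ls) {
    pair_key(ls$positives$a, ls$positives$b)
  })
  out <- lapply(stats::setNames(o$terms$id, o$terms$id), function(t) {
    ls <- train_labels[[t]]
    ch <- o$children[[t]]
    lab_pairs <- rbind(ls$positives, ls$negatives)
    lab_is_pos <- rep(c(TRUE, FALSE),
                      c(nrow(ls$positives), nrow(ls$negatives)))
    any_child_pos <- rep(FALSE, nrow(lab_pairs))
    for (c_id in ch) {
      hit <- pairs_in(lab_pairs, pos_keys[[c_id]], ls$directed,
                      is_directed_term(o, c_id))
      bad <- hit & !lab_is_pos
      if (any(bad)) {
        ex <- lab_pairs[bad, , drop = FALSE][1, ]
        stop(sprintf(
          "hierarchy violation at '%s': %d pair(s) positive at child '%s' but negative at the parent (e.g. %s-%s)",
          t, sum(bad), c_id, ex$a, ex$b))
      }
      any_child_pos <- any_child_pos | hit
    }
    n <- sum(!any_child_pos)
    k <- sum(!any_child_pos & lab_is_pos)
    structure(list(term = t, children = ch,
                   q = (k + a) / (n + 2 * a), n = n),
              class = "structural_cpt")
  })
  out
}

#' @export
print.structural_cpt <- function(x, ...) {
  cat(sprintf("structural CPT '%s': %d children, P(on | all children off) = %.4f (n = %d)\n",
              x$term, length(x$children), x$q, x$n))
  invisible(x)
}

#' Hierarchical reconciliation model
#'
#' Bundles everything needed to turn per-term bagged scores into
#' hierarchically consistent posteriors: the modeled ontology, one
#' discretization scheme and observation CPT per term, and the structural
#' CPTs encoding the hierarchy constraints.
#'
#' @param ontology the modeled `interaction_ontology`.
#' @param discretizers named list of `discretization_scheme`s.
#' @param observation named list of `observation_cpt`s.
#' @param structure named list of `structural_cpt`s.
#' @return object of class `hierarchical_model`.
#' @export
hierarchical_model <- function(ontology, discretizers, observation,
                               structure) {
  ids <- ontology$terms$id
  for (part in list(discretizers, observation, structure)) {
    if (length(setdiff(ids, names(part)))) {
      stop("model components must cover every modeled term")
    }
  }
  base::structure(list(ontology = ontology, discretizers = discretizers,
                       observation = observation, structure = structure,
                       terms = ids),
                  class = "hierarchical_model")
}

#' @export
print.hierarchical_model <- function(x, ...) {
  cat(sprintf("hierarchical model over %d terms (root '%s')\n",
              length(x$terms), x$ontology$root))
  invisible(x)
}

# Per-term evidence likelihoods P(y_obs | X = 0/1) for a score vector with
# possible NAs (unobserved evidence contributes a constant factor).
evidence_likelihoods <- function(model, term, scores, missing_action) {
  n <- length(scores)
  L0 <- rep(1, n)
  L1 <- rep(1, n)
  obs <- !is.na(scores)
  if (!all(obs) && missing_action == "error") {
    stop(sprintf("term '%s': %d pair(s) have no score", term, sum(!obs)))
  }
  if (any(obs)) {
    b <- discretize(model$discretizers[[term]], scores[obs])
    p <- model$observation[[term]]$p
    L0[obs] <- p[b, "0"]
    L1[obs] <- p[b, "1"]
  }
  list(L0 = L0, L1 = L1)
}

#' Exact hierarchically consistent posteriors
#'
#' Computes, for every gene pair and term, the exact marginal posterior
#' P(X_term = 1 | all discretized scores) by sum-product message passing on
#' the decorated tree. The constrained structural CPT
#' (any child on => parent on) factorizes, so messages cost O(#children)
#' per term and fan-in is unlimited; posteriors automatically satisfy
#' posterior(parent) >= posterior(child).
#'
#' @param model a `hierarchical_model`.
#' @param scores either a named list of `score_table`s (one per modeled
#'   term, all over the same ordered pair sequence) or a numeric matrix
#'   (pairs x terms) together with `pairs`.
#' @param pairs data.frame of gene pairs (required when `scores` is a
#'   matrix).
#' @param missing how to treat a missing (NA) score: `"marginalize"`
#'   (treat Y as unobserved) or `"error"`.
#' @return object of class `posterior_table`: `pairs` plus matrix
#'   `posterior` (pairs x terms) of P(X = 1 | evidence).
#' @export
infer_posteriors <- function(model, scores, pairs = NULL,
                             missing = c("marginalize", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(model, "hierarchical_model"))
  sm <- as_score_matrix(model, scores, pairs)
  pairs <- sm$pairs
  S <- sm$scores
  n <- nrow(pairs)
  o <- model$ontology

  L <- lapply(stats::setNames(model$terms, model$terms), function(t) {
    evidence_likelihoods(model, t, S[, t], missing)
  })

  # Upward pass (children before parents): alpha_t(x) proportional to
  # P(evidence in subtree of t, X_t = x), normalized per pair for
  # numerical stability.
  alpha0 <- list()
  alpha1 <- list()
  for (t in postorder_terms(o)) {
    q <- model$structure[[t]]$q
    ch <- o$children[[t]]
    if (length(ch) == 0L) {
      a0 <- L[[t]]$L0 * (1 - q)
      a1 <- L[[t]]$L1 * q
    } else {
      A0 <- rep(1, n)
      Sprod <- rep(1, n)
      for (c_id in ch) {
        A0 <- A0 * alpha0[[c_id]]
        Sprod <- Sprod * (alpha0[[c_id]] + alpha1[[c_id]])
      }
      a0 <- L[[t]]$L0 * (1 - q) * A0
      a1 <- L[[t]]$L1 * (Sprod - (1 - q) * A0)
    }
    z <- a0 + a1
    alpha0[[t]] <- a0 / z
    alpha1[[t]] <- a1 / z
  }

  # Downward pass: m_t(x) proportional to P(evidence outside subtree of t |
  # X_t = x); posterior_t proportional to alpha_t * m_t.
  m0 <- list()
  m1 <- list()
  m0[[o$root]] <- rep(1, n)
  m1[[o$root]] <- rep(1, n)
  post <- matrix(NA_real_, n, length(model$terms),
                 dimnames = list(NULL, model$terms))
  for (t in rev(postorder_terms(o))) {
    num1 <- alpha1[[t]] * m1[[t]]
    num0 <- alpha0[[t]] * m0[[t]]
    post[, t] <- num1 / (num0 + num1)
    ch <- o$children[[t]]
    if (length(ch) == 0L) next
    q <- model$structure[[t]]$q
    A0 <- rep(1, n)
    Sprod <- rep(1, n)
    for (c_id in ch) {
      A0 <- A0 * alpha0[[c_id]]
      Sprod <- Sprod * (alpha0[[c_id]] + alpha1[[c_id]])
    }
    for (c_id in ch) {
      A0mc <- A0 / alpha0[[c_id]]
      Smc <- Sprod / (alpha0[[c_id]] + alpha1[[c_id]])
      mc0 <- m0[[t]] * L[[t]]$L0 * (1 - q) * A0mc +
        m1[[t]] * L[[t]]$L1 * (Smc - (1 - q) * A0mc)
      mc1 <- m1[[t]] * L[[t]]$L1 * Smc
      z <- mc0 + mc1
      m0[[c_id]] <- mc0 / z
      m1[[c_id]] <- mc1 / z
    }
  }
  structure(list(pairs = pairs, posterior = post),
            class = "posterior_table")
}

as_score_matrix <- function(model, scores, pairs) {
  if (is.matrix(scores)) {
    if (is.null(pairs)) stop("`pairs` is required when scores is a matrix")
    missing <- setdiff(model$terms, colnames(scores))
    if (length(missing)) {
      stop("score matrix missing term(s): ", paste(missing, collapse = ", "))
    }
    return(list(pairs = new_pairs(pairs$a, pairs$b),
                scores = scores[, model$terms, drop = FALSE]))
  }
  missing <- setdiff(model$terms, names(scores))
  if (length(missing)) {
    stop("scores missing for term(s): ", paste(missing, collapse = ", "))
  }
  ref <- scores[[model$terms[1]]]$pairs
  refk <- pair_key(ref$a, ref$b)
  S <- matrix(NA_real_, nrow(ref), length(model$terms),
              dimnames = list(NULL, model$terms))
  for (t in model$terms) {
    st <- scores[[t]]
    if (!identical(pair_key(st$pairs$a, st$pairs$b), refk)) {
      stop("score tables are not aligned on the same pair sequence")
    }
    S[, t] <- st$scores
  }
  list(pairs = ref, scores = S)
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("posterior table: %d pairs x %d terms\n",
              nrow(x$pairs), ncol(x$posterior)))
  invisible(x)
}

#' Joint MAP label assignment (max-product)
#'
#' Secondary output mode: the single most probable joint configuration of
#' all latent labels per pair, computed by max-product with backtracking.
#' The assignment is hierarchy-consistent by construction (a child can only
#' be on when its parent is on).
#'
#' @inheritParams infer_posteriors
#' @return logical matrix (pairs x terms): the jointly most probable label
#'   assignment per pair.
#' @export
map_assignment <- function(model, scores, pairs = NULL,
                           missing = c("marginalize", "error")) {
  missing <- match.arg(missing)
  sm <- as_score_matrix(model, scores, pairs)
  n <- nrow(sm$pairs)
  o <- model$ontology
  L <- lapply(stats::setNames(model$terms, model$terms), function(t) {
    evidence_likelihoods(model, t, sm$scores[, t], missing)
  })
  out <- matrix(NA, n, length(model$terms),
                dimnames = list(NULL, model$terms))
  order_up <- postorder_terms(o)
  for (i in seq_len(n)) {
    mu <- list()   # per-term c(best score | x=0, | x=1)
    choice <- list()  # per-term, per own state: children states
    for (t in order_up) {
      q <- model$structure[[t]]$q
      ch <- o$children[[t]]
      l0 <- L[[t]]$L0[i]
      l1 <- L[[t]]$L1[i]
      if (length(ch) == 0L) {
        mu[[t]] <- c(l0 * (1 - q), l1 * q)
        choice[[t]] <- list(`0` = logical(0), `1` = logical(0))
      } else {
        m0c <- vapply(ch, function(c_id) mu[[c_id]][1], 0)
        m1c <- vapply(ch, function(c_id) mu[[c_id]][2], 0)
        # x_t = 0 forces all children off
        v0 <- l0 * (1 - q) * prod(m0c)
        ch0 <- rep(FALSE, length(ch))
        # x_t = 1: either all children off (prob q) or >= 1 child on
        best <- pmax(m0c, m1c)
        on_best <- m1c >= m0c
        v_alloff <- q * prod(m0c)
        if (any(on_best)) {
          v_someon <- prod(best)
          ch_on <- on_best
        } else {
          j <- which.max(m1c / m0c)
          v_someon <- prod(m0c) / m0c[j] * m1c[j]
          ch_on <- rep(FALSE, length(ch))
          ch_on[j] <- TRUE
        }
        if (v_alloff >= v_someon) {
          v1 <- l1 * v_alloff
          ch1 <- rep(FALSE, length(ch))
        } else {
          v1 <- l1 * v_someon
          ch1 <- ch_on
        }
        mu[[t]] <- c(v0, v1)
        choice[[t]] <- list(`0` = ch0, `1` = ch1)
      }
    }
    # backtrack from the ontology root
    x <- stats::setNames(rep(NA, length(model$terms)), model$terms)
    x[o$root] <- mu[[o$root]][2] >= mu[[o$root]][1]
    for (t in rev(order_up)) {
      ch <- o$children[[t]]
      if (!length(ch)) next
      st <- choice[[t]][[if (x[t]) "1" else "0"]]
      x[ch] <- st
    }
    out[i, ] <- x
  }
  out
}

#' Full prediction pipeline: score, discretize, reconcile
#'
#' Composes the per-term bagged classifiers with the Bayesian
#' reconciliation for a shared pair sequence. For undirected terms the
#' feature construction is orientation-invariant, so an ordered query pair
#' receives identical evidence (hence identical posteriors) under either
#' orientation; directed terms treat each orientation as its own instance.
#'
#' @param model a `hierarchical_model`.
#' @param classifiers named list of `bagged_classifier`s per term.
#' @param features named list of `feature_table`s per term, all over the
#'   same ordered pair sequence.
#' @return a `posterior_table`.
#' @export
predict_pipeline <- function(model, classifiers, features) {
  missing <- setdiff(model$terms, names(classifiers))
  if (length(missing)) {
    stop("classifiers missing for term(s): ", paste(missing, collapse = ", "))
  }
  scores <- lapply(stats::setNames(model$terms, model$terms), function(t) {
    predict_scores(classifiers[[t]], features[[t]])
  })
  infer_posteriors(model, scores)
}
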
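#' Per-term labeled gene-pair sets
#'
#' A `pair_label_set` holds the gold standard for one interaction type:
#' disjoint positive and negative gene pairs, ordered if the term is
#' directed and stored in canonical (lexicographic) order otherwise.
#' Self-pairs are forbidden throughout.
#'
#' @param term term id.
#' @param positives,negatives data.frames with character columns `a`, `b`.
#' @param directed logical; whether pairs are ordered.
#' @return an object of class `pair_label_set`.
#' @export
pair_label_set <- function(term, positives, negatives = new_pairs(),
                           directed = FALSE) {
  positives <- as_pairs(positives, directed)
  negatives <- as_pairs(negatives, directed)
  both <- intersect(pair_key(positives$a, positives$b),
                    pair_key(negatives$a, negatives$b))
  if (length(both)) {
    stop(sprintf("term '%s': %d pair(s) labeled both positive and negative",
                 term, length(both)))
  }
  structure(list(term = term, directed = directed,
                 positives = positives, negatives = negatives),
            class = "pair_label_set")
}

as_pairs <- function(pairs, directed) {
  pairs <- new_pairs(pairs$a, pairs$b)
  if (any(pairs$a == pairs$b)) {
    stop("self-pairs are not allowed: ",
         paste(utils::head(pairs$a[pairs$a == pairs$b], 3), collapse = ", "))
  }
  if (!directed) pairs <- canonicalize_pairs(pairs)
  pairs <- dedup_pairs(pairs)
  rownames(pairs) <- NULL
  pairs
}

#' @export
print.pair_label_set <- function(x, ...) {
  cat(sprintf("pair_label_set '%s' (%s): %d positives, %d negatives\n",
              x$term, if (x$directed) "directed" else "undirected",
              nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

# Membership of pairs (stored under `from_directed` semantics) in a key set
# built under `to_directed` semantics.
pairs_in <- function(pairs, keys, from_directed, to_directed) {
  if (nrow(pairs) == 0L) return(logical(0))
  if (!to_directed) {
    p <- canonicalize_pairs(pairs)
    pair_key(p$a, p$b) %in% keys
  } else if (from_directed) {
    pair_key(pairs$a, pairs$b) %in% keys
  } else {
    # An unordered pair counts as positive at a directed term if either
    # orientation is annotated.
    pair_key(pairs$a, pairs$b) %in% keys | pair_key(pairs$b, pairs$a) %in% keys
  }
}

#' True-path propagation of positive annotations
#'
#' Copies each positive gene pair to every ancestor term so that labels are
#' hierarchy-consistent. An ordered pair contributed to an undirected
#' ancestor is canonicalized; an unordered pair propagated to a directed
#' ancestor keeps its stored (canonical) order and is never assigned a
#' direction.
#'
#' @param o an `interaction_ontology`.
#' @param raw named list, term id -> data.frame of positive pairs (`a`,
#'   `b`); terms absent from `raw` contribute nothing.
#' @return named list over all terms of `o` (ontology order): propagated
#'   positive pair data.frames.
#' @export
propagate_positives <- function(o, raw) {
  check_term(o, names(raw))
  acc <- lapply(stats::setNames(o$terms$id, o$terms$id), function(t) {
    directed <- is_directed_term(o, t)
    p <- raw[[t]] %||% new_pairs()
    as_pairs(p, directed)
  })
  for (t in postorder_terms(o)) {
    parent <- o$terms$parent[match(t, o$terms$id)]
    if (is.na(parent)) next
    contrib <- acc[[t]]
    if (!is_directed_term(o, parent)) contrib <- canonicalize_pairs(contrib)
    acc[[parent]] <- dedup_pairs(rbind(acc[[parent]], contrib))
  }
  lapply(acc, function(p) { rownames(p) <- NULL; p })
}

#' Sample matched negative gene pairs
#'
#' Draws `n` pairs uniformly at random from all non-self pairs over
#' `universe` that are not positives, mirroring the equal-size negative
#' standard used for sparse interaction data.
#'
#' @param positives data.frame of positive pairs (`a`, `b`).
#' @param universe character vector of gene ids to draw from.
#' @param n number of negatives (conventionally `nrow(positives)`).
#' @param seed integer; fixes the draw.
#' @param directed logical; sample ordered pairs if `TRUE`.
#' @return data.frame of `n` negative pairs (canonical order if
#'   undirected), disjoint from `positives`.
#' @export
sample_negatives <- function(positives, universe, n, seed = 1,
                             directed = FALSE) {
  universe <- sort(unique(as.character(universe)))
  g <- length(universe)
  total <- if (directed) g * (g - 1) else g * (g - 1) / 2
  pos <- as_pairs(positives, directed)
  pos_keys <- pair_key(pos$a, pos$b)
  pos_inside <- sum(pos$a %in% universe & pos$b %in% universe)
  avail <- total - pos_inside
  if (n > avail) {
    stop(sprintf(
      "cannot sample %d negatives: only %d eligible pairs (%d total, %d positive)",
      n, avail, total, pos_inside))
  }
  if (n == 0L) return(new_pairs())

  idx_to_pair <- function(idx) {
    # idx is 1-based over the ordered enumeration of pairs
    if (directed) {
      i <- (idx - 1L) %/% (g - 1L) + 1L
      j <- (idx - 1L) %% (g - 1L) + 1L
      j <- ifelse(j >= i, j + 1L, j)
    } else {
      # row-major upper triangle
      i <- findInterval(idx - 1L, cumsum(c(0, (g - 1L):1L)),
                        rightmost.closed = FALSE)
      offset <- idx - c(0, cumsum((g - 1L):1L))[i]
      j <- i + offset
    }
    new_pairs(universe[i], universe[j])
  }

  with_seed(seed, {
    if (total <= 2e6) {
      all_pairs <- idx_to_pair(seq_len(total))
      keep <- !(pair_key(all_pairs$a, all_pairs$b) %in% pos_keys)
      elig <- all_pairs[keep, , drop = FALSE]
      out <- elig[sample(nrow(elig), n), , drop = FALSE]
    } else {
      # Rejection sampling: uniform over eligible pairs without enumeration.
      chosen <- character(0)
      out <- new_pairs()
      while (nrow(out) < n) {
        m <- max(2L * (n - nrow(out)), 1000L)
        cand <- idx_to_pair(sample.int(total, m, replace = TRUE))
        keys <- pair_key(cand$a, cand$b)
        ok <- !(keys %in% pos_keys) & !(keys %in% chosen) & !duplicated(keys)
        cand <- cand[ok, , drop = FALSE]
        take <- utils::head(cand, n - nrow(out))
        chosen <- c(chosen, pair_key(take$a, take$b))
        out <- rbind(out, take)
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Direction-flipped negatives for a directed term
#'
#' For each ordered positive (a, b) the flipped pair (b, a) is a negative
#' example of incorrect directionality. Pairs whose flip is itself a
#' positive (bidirectional positives) are excluded and reported via the
#' `"excluded"` attribute.
#'
#' @param positives data.frame of ordered positive pairs.
#' @param directed must be `TRUE`; calling this for an undirected term's
#'   labels is a contract error.
#' @return data.frame of flipped pairs with attribute `excluded` (the
#'   positives dropped because their flip is also annotated).
#' @export
make_direction_negatives <- function(positives, directed = TRUE) {
  if (!isTRUE(directed)) {
    stop("direction-flipped negatives are only defined for directed terms")
  }
  pos <- as_pairs(positives, directed = TRUE)
  keys <- pair_key(pos$a, pos$b)
  bidir <- pair_key(pos$b, pos$a) %in% keys
  flipped <- flip_pairs(pos[!bidir, , drop = FALSE])
  rownames(flipped) <- NULL
  structure(flipped, excluded = pos[bidir, , drop = FALSE])
}

#' Train/test split by gene exclusion
#'
#' Draws a holdout set H of `ceiling(holdout_fraction * n_genes)` genes
#' from the genes appearing in `labels`. Test pairs touch at least one gene
#' of H; training pairs touch none, so train and test share no held-out
#' gene. Every labeled pair lands in exactly one side.
#'
#' @param labels a `pair_label_set`.
#' @param holdout_fraction proportion of genes to hold out (0 < f < 1).
#' @param seed integer seed for the gene draw.
#' @param holdout_genes optional pre-drawn holdout gene set (overrides the
#'   draw; used to share one split across terms).
#' @return list with `train` and `test` (`pair_label_set`s) and
#'   `holdout` (the gene set H).
#' @export
split_by_gene <- function(labels, holdout_fraction = 0.3, seed = 1,
                          holdout_genes = NULL) {
  stopifnot(inherits(labels, "pair_label_set"))
  if (is.null(holdout_genes)) {
    if (holdout_fraction <= 0 || holdout_fraction >= 1) {
      stop("holdout_fraction must be strictly between 0 and 1")
    }
    genes <- sort(unique(c(pair_genes(labels$positives),
                           pair_genes(labels$negatives))))
    n_hold <- ceiling(holdout_fraction * length(genes))
    holdout_genes <- with_seed(seed, sample(genes, n_hold))
  }
  touches <- function(p) p$a %in% holdout_genes | p$b %in% holdout_genes
  pos_t <- touches(labels$positives)
  neg_t <- touches(labels$negatives)
  train <- pair_label_set(labels$term,
                          labels$positives[!pos_t, , drop = FALSE],
                          labels$negatives[!neg_t, , drop = FALSE],
                          labels$directed)
  test <- pair_label_set(labels$term,
                         labels$positives[pos_t, , drop = FALSE],
                         labels$negatives[neg_t, , drop = FALSE],
                         labels$directed)
  if (nrow(train$positives) + nrow(train$negatives) == 0L ||
      nrow(test$positives) + nrow(test$negatives) == 0L) {
    warning(sprintf(
      "term '%s': degenerate split (train %d+%d, test %d+%d pairs)",
      labels$term, nrow(train$positives), nrow(train$negatives),
      nrow(test$positives), nrow(test$negatives)))
  }
  list(train = train, test = test, holdout = holdout_genes)
}

#' Read / write per-term label files
#'
#' TSV format `gene_a <TAB> gene_b <TAB> term_id <TAB> label(+1/-1)`; for
#' directed terms the column order encodes direction (a -> b). The writer
#' mirrors the reader bit-exactly.
#'
#' @param path file path.
#' @param o an `interaction_ontology` supplying each term's directedness.
#' @return `read_pair_labels()` returns a named list of `pair_label_set`s
#'   (one per term present in the file).
#' @export
read_pair_labels <- function(path, o) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", quote = "",
                         comment.char = "#")
  if (ncol(d) != 4L) stop("label file must have 4 tab-separated columns")
  names(d) <- c("a", "b", "term", "label")
  if (!all(d$label %in% c("1", "+1", "-1"))) {
    stop("labels must be +1 or -1")
  }
  check_term(o, unique(d$term))
  out <- lapply(split(d, d$term), function(dd) {
    directed <- is_directed_term(o, dd$term[1])
    pos <- dd[dd$label %in% c("1", "+1"), c("a", "b")]
    neg <- dd[dd$label == "-1", c("a", "b")]
    pair_label_set(dd$term[1], pos, neg, directed)
  })
  out[order(match(names(out), o$terms$id))]
}

#' @rdname read_pair_labels
#' @param labels a named list of `pair_label_set`s (or a single one).
#' @export
write_pair_labels <- function(labels, path) {
  if (inherits(labels, "pair_label_set")) labels <- list(labels)
  lines <- unlist(lapply(labels, function(ls) {
    c(if (nrow(ls$positives)) sprintf("%s\t%s\t%s\t+1", ls$positives$a,
                                      ls$positives$b, ls$term),
      if (nrow(ls$negatives)) sprintf("%s\t%s\t%s\t-1", ls$negatives$a,
                                      ls$negatives$b, ls$term))
  }), use.names = FALSE)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
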
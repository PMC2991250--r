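#' Per-pair feature tables
#'
#' A `feature_table` holds one row of real-valued features per gene pair.
#' Every column carries a source tag from the fixed vocabulary
#' (`expression`, `colocalization`, `family`, `binding-profile`,
#' `similarity`) so that sources related to a predicted interaction type
#' can be excluded wholesale.
#'
#' @param pairs data.frame of gene pairs (`a`, `b`), one per row.
#' @param values numeric matrix, `nrow(pairs)` rows; unique column names.
#' @param sources character vector of source tags, one per column.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(pairs, values, sources) {
  stopifnot(is.data.frame(pairs), is.matrix(values),
            nrow(values) == nrow(pairs),
            length(sources) == ncol(values))
  vocab <- c("expression", "colocalization", "family", "binding-profile",
             "similarity")
  bad <- setdiff(unique(sources), vocab)
  if (length(bad)) {
    stop("unknown feature source tag(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("feature columns must have unique names")
  }
  if (any(!is.finite(values))) stop("feature values must be finite")
  rownames(values) <- NULL
  structure(list(pairs = new_pairs(pairs$a, pairs$b), values = values,
                 sources = as.character(sources)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature table: %d pairs x %d features [%s]\n",
              nrow(x$pairs), ncol(x$values),
              paste(unique(x$sources), collapse = ", ")))
  invisible(x)
}

#' Expression-difference features
#'
#' One feature per condition: for a directed pair (i, j) the signed
#' difference x_i - x_j (antisymmetric in orientation), for an undirected
#' pair the absolute difference |x_i - x_j|.
#'
#' @param c an imputed `expression_compendium` (no missing values).
#' @param pairs data.frame of gene pairs.
#' @param directed logical; signed differences if `TRUE`.
#' @return a `feature_table` with one `expression`-tagged column per
#'   condition.
#' @export
pair_features_expression <- function(c, pairs, directed = FALSE) {
  stopifnot(inherits(c, "expression_compendium"))
  if (anyNA(c$values)) stop("expression compendium contains missing values; impute first")
  missing <- setdiff(unique(c(pairs$a, pairs$b)), rownames(c$values))
  if (length(missing)) {
    stop("gene(s) absent from expression compendium: ",
         paste(missing, collapse = ", "))
  }
  d <- c$values[pairs$a, , drop = FALSE] - c$values[pairs$b, , drop = FALSE]
  if (!directed) d <- abs(d)
  colnames(d) <- paste0("expr:", colnames(c$values))
  feature_table(pairs, d, rep("expression", ncol(d)))
}

#' Shared-annotation indicator feature
#'
#' Binary feature: 1 when the two genes' category sets (e.g. subcellular
#' compartments, protein families) intersect. Genes absent from
#' `membership` have the empty set.
#'
#' @param membership named list, gene id -> character vector of categories.
#' @param pairs data.frame of gene pairs.
#' @param feature_name column name for the feature.
#' @param source source tag (default `"colocalization"`; use `"family"`
#'   for protein-family tables).
#' @return a single-column `feature_table`.
#' @export
pair_features_shared <- function(membership, pairs,
                                 feature_name = "shared",
                                 source = "colocalization") {
  get_set <- function(g) membership[[g]] %||% character(0)
  v <- mapply(function(a, b) {
    as.numeric(length(intersect(get_set(a), get_set(b))) > 0)
  }, pairs$a, pairs$b, USE.NAMES = FALSE)
  m <- matrix(v, ncol = 1, dimnames = list(NULL, feature_name))
  feature_table(pairs, m, source)
}

#' Binding-profile distance feature
#'
#' Euclidean distance between the two genes' binding-site profiles (e.g.
#' per-transcription-factor scores). Genes without a profile either raise
#' an error or receive the mean distance over computable pairs.
#'
#' @param profiles numeric matrix, rownames = gene ids (all profiles the
#'   same length by construction).
#' @param pairs data.frame of gene pairs.
#' @param missing `"error"` or `"mean"` handling of absent profiles.
#' @return a single-column `feature_table` tagged `binding-profile`.
#' @export
pair_features_profile_distance <- function(profiles, pairs,
                                           missing = c("error", "mean")) {
  missing <- match.arg(missing)
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  have <- pairs$a %in% rownames(profiles) & pairs$b %in% rownames(profiles)
  if (!all(have) && missing == "error") {
    absent <- setdiff(unique(c(pairs$a, pairs$b)), rownames(profiles))
    stop("gene(s) without binding profile: ", paste(absent, collapse = ", "))
  }
  v <- rep(NA_real_, nrow(pairs))
  if (any(have)) {
    dd <- profiles[pairs$a[have], , drop = FALSE] -
      profiles[pairs$b[have], , drop = FALSE]
    v[have] <- sqrt(rowSums(dd^2))
  }
  if (any(!have)) {
    fill <- if (any(have)) mean(v[have]) else 0
    message(sum(!have), " pair(s) without binding profiles; using mean distance")
    v[!have] <- fill
  }
  m <- matrix(v, ncol = 1, dimnames = list(NULL, "binding_profile_dist"))
  feature_table(pairs, m, "binding-profile")
}

#' Sequence-similarity feature from precomputed E-values
#'
#' Alignment E-values span many decades, so they enter as
#' `-log10(pmax(E, floor))`; pairs absent from the score table get E = 1
#' (no detectable similarity, feature 0).
#'
#' @param evalues data.frame with columns `a`, `b`, `evalue` (unordered;
#'   looked up under canonical order).
#' @param pairs data.frame of gene pairs.
#' @param floor smallest E-value before flooring (default 1e-200).
#' @return a single-column `feature_table` tagged `similarity`.
#' @export
pair_features_similarity <- function(evalues, pairs, floor = 1e-200) {
  ev <- canonicalize_pairs(new_pairs(evalues$a, evalues$b))
  lut <- stats::setNames(as.numeric(evalues$evalue), pair_key(ev$a, ev$b))
  p <- canonicalize_pairs(new_pairs(pairs$a, pairs$b))
  e <- lut[pair_key(p$a, p$b)]
  e[is.na(e)] <- 1
  m <- matrix(-log10(pmax(e, floor)), ncol = 1,
              dimnames = list(NULL, "seq_similarity"))
  feature_table(pairs, m, "similarity")
}

#' Assemble per-term feature tables with related-data exclusion
#'
#' Column-concatenates feature tables over the same pair sequence, dropping
#' every column whose source tag is excluded for the predicted term (e.g.
#' binding profiles when predicting regulatory relationships). Column order
#' follows `sources` order, so a fixed configuration yields an identical
#' layout every time.
#'
#' @param sources list of `feature_table`s over the same pairs, in order.
#' @param exclude character vector of source tags to drop (may be empty).
#' @return a `feature_table`.
#' @export
assemble_features <- function(sources, exclude = character()) {
  stopifnot(length(sources) >= 1)
  ref <- pair_key(sources[[1]]$pairs$a, sources[[1]]$pairs$b)
  for (s in sources[-1]) {
    if (!identical(pair_key(s$pairs$a, s$pairs$b), ref)) {
      stop("feature tables are not aligned on the same pair sequence")
    }
  }
  vals <- list()
  tags <- character(0)
  for (s in sources) {
    keep <- !(s$sources %in% exclude)
    if (any(keep)) {
      vals[[length(vals) + 1L]] <- s$values[, keep, drop = FALSE]
      tags <- c(tags, s$sources[keep])
    }
  }
  if (!length(vals)) stop("all feature columns excluded for this term")
  feature_table(sources[[1]]$pairs, do.call(cbind, vals), tags)
}

#' Look up a term's excluded source tags
#'
#' @param exclusions named list, term id -> character vector of source tags
#'   to withhold when predicting that term.
#' @param term term id.
#' @return character vector (empty when the term has no exclusions).
#' @export
excluded_sources <- function(exclusions, term) {
  as.character(exclusions[[term]] %||% character(0))
}

#' Column standardization fitted on training pairs
#'
#' Margin classifiers need comparable feature scales; `fit_standardizer()`
#' learns per-column mean and standard deviation on training rows and
#' `apply_standardizer()` maps any aligned table to zero mean / unit
#' variance under those parameters (constant columns get scale 1).
#'
#' @param ft a `feature_table` of training pairs.
#' @return `fit_standardizer()`: list with `center` and `scale`;
#'   `apply_standardizer()`: a standardized `feature_table`.
#' @export
fit_standardizer <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  center <- colMeans(ft$values)
  scale <- apply(ft$values, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

#' @rdname fit_standardizer
#' @param s a standardizer from `fit_standardizer()`.
#' @export
apply_standardizer <- function(ft, s) {
  if (!identical(names(s$center), colnames(ft$values))) {
    stop("standardizer columns do not match feature table columns")
  }
  v <- sweep(sweep(ft$values, 2, s$center), 2, s$scale, "/")
  feature_table(ft$pairs, v, ft$sources)
}
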
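#' Expression compendia
#'
#' A gene-by-condition matrix of (log-ratio) intensities, with conditions
#' grouped by dataset of origin and `NA` marking missing measurements.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = condition
#'   ids.
#' @param dataset character/factor of length `ncol(values)` giving each
#'   condition's dataset of origin (defaults to one dataset).
#' @return object of class `expression_compendium`.
#' @export
expression_compendium <- function(values, dataset = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (is.null(dataset)) dataset <- rep("d1", ncol(values))
  stopifnot(length(dataset) == ncol(values))
  structure(list(values = values, dataset = as.character(dataset)),
            class = "expression_compendium")
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("expression compendium: %d genes x %d conditions (%d datasets), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), length(unique(x$dataset)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read a tab-delimited (PCL-like) expression matrix
#'
#' First column gene id, header row of condition ids, `NA` or empty cells
#' missing. PCL-style annotation columns (NAME, GWEIGHT, ...) following the
#' gene id can be skipped with `skip_annotation_cols`.
#'
#' @param path file path.
#' @param skip_annotation_cols number of annotation columns after the gene
#'   id column to drop (default 0).
#' @param dataset dataset-of-origin label(s) for the conditions.
#' @return an `expression_compendium`.
#' @export
read_expression <- function(path, skip_annotation_cols = 0, dataset = NULL) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         check.names = FALSE, comment.char = "",
                         na.strings = c("NA", ""), stringsAsFactors = FALSE)
  genes <- as.character(d[[1]])
  keep <- setdiff(seq_len(ncol(d)), seq_len(1 + skip_annotation_cols))
  m <- as.matrix(d[, keep, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_compendium(m, dataset)
}

#' k-nearest-neighbour imputation of missing expression values
#'
#' Genes missing more than `max_missing` of their conditions (over the
#' whole compendium) are removed and recorded in the `dropped` attribute.
#' Each remaining missing entry is replaced, within its dataset of origin,
#' by the average of that condition's values over the `k` genes nearest in
#' Euclidean distance (normalized per mutually observed condition) that
#' have the condition observed. With fewer than `k` usable neighbours the
#' available ones are used with a warning; with none, the condition mean
#' (or, failing that, the gene mean) is used.
#'
#' @param c an `expression_compendium`.
#' @param k number of neighbours (default 10).
#' @param max_missing maximum tolerated per-gene missing fraction
#'   (default 0.3).
#' @return an `expression_compendium` with no missing entries and attribute
#'   `dropped` (gene ids removed by the missingness rule). Observed entries
#'   are never altered.
#' @export
knn_impute <- function(c, k = 10, max_missing = 0.3) {
  stopifnot(inherits(c, "expression_compendium"), k >= 1)
  v <- c$values
  frac <- rowMeans(is.na(v))
  dropped <- rownames(v)[frac > max_missing]
  v <- v[frac <= max_missing, , drop = FALSE]

  short <- FALSE
  for (ds in unique(c$dataset)) {
    cols <- which(c$dataset == ds)
    block <- v[, cols, drop = FALSE]
    miss <- which(is.na(block), arr.ind = TRUE)
    if (nrow(miss) == 0L) next
    if (nrow(block) == 1L) {
      # single-gene dataset: no neighbours exist; use the gene's mean
      block[is.na(block)] <- mean(block, na.rm = TRUE)
      v[, cols] <- block
      next
    }
    need <- unique(miss[, 1])
    obs <- !is.na(block)
    for (g in need) {
      # squared distance per shared condition against every other gene
      diffs <- sweep(block, 2, block[g, ])^2
      shared <- obs & rep(obs[g, ], each = nrow(block))
      d2 <- rowSums(ifelse(shared, diffs, 0), na.rm = TRUE)
      nsh <- rowSums(shared)
      dist <- sqrt(d2 / pmax(nsh, 1))
      dist[nsh == 0] <- Inf
      dist[g] <- Inf
      for (cc in which(is.na(block[g, ]))) {
        cand <- which(obs[, cc] & is.finite(dist))
        if (length(cand) == 0L) {
          colv <- block[, cc]
          fill <- if (all(is.na(colv))) mean(block[g, ], na.rm = TRUE)
                  else mean(colv, na.rm = TRUE)
          block[g, cc] <- fill
          next
        }
        if (length(cand) < k) short <- TRUE
        nb <- cand[order(dist[cand], cand)][seq_len(min(k, length(cand)))]
        block[g, cc] <- mean(block[nb, cc])
      }
    }
    v[, cols] <- block
  }
  if (short) {
    warning("fewer than k usable neighbour genes for some entries; ",
            "used all available neighbours")
  }
  out <- expression_compendium(v, c$dataset)
  attr(out, "dropped") <- dropped
  out
}
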
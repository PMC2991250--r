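#' Synthetic study configuration
#'
#' Defines the conditions under which the synthetic benchmark is generated:
#' a complete interaction-type tree, hierarchy-consistent planted labels,
#' and per-term informative feature columns with controllable
#' signal-to-noise. Defaults describe the package's reference study: a
#' 2-level, 8-term ontology (root plus 7 leaves, 40% of leaves directed)
#' over 500 genes, sparse positives (0.5% of pairs per leaf), effect sizes
#' spread over {0.5, 1, 2} so that borrowing strength across the hierarchy
#' is observable, 4 informative columns per term plus 20 shared noise
#' columns at unit noise.
#'
#' @param n_genes number of genes in the universe.
#' @param depth,branching shape of the complete term tree below the root.
#' @param frac_directed fraction of leaf terms that are directed.
#' @param pos_rate per-leaf probability that a gene pair is a positive.
#' @param delta per-term signal shifts, recycled over terms in ontology
#'   order.
#' @param n_informative informative feature columns per term.
#' @param n_noise shared pure-noise columns.
#' @param noise_sd feature noise standard deviation.
#' @param missing_rate missingness rate for the mock expression compendium
#'   (imputation tests only).
#' @param seed default seed for all generator draws.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genes = 500, depth = 1, branching = 7,
                         frac_directed = 0.4, pos_rate = 0.005,
                         delta = c(0.5, 1, 2), n_informative = 4,
                         n_noise = 20, noise_sd = 1, missing_rate = 0,
                         seed = 1) {
  stopifnot(n_genes >= 3, depth >= 1, branching >= 1,
            frac_directed >= 0, frac_directed <= 1,
            pos_rate >= 0, pos_rate <= 1, n_informative >= 1,
            noise_sd > 0, missing_rate >= 0, missing_rate <= 1)
  structure(list(n_genes = n_genes, depth = depth, branching = branching,
                 frac_directed = frac_directed, pos_rate = pos_rate,
                 delta = delta, n_informative = n_informative,
                 n_noise = n_noise, noise_sd = noise_sd,
                 missing_rate = missing_rate, seed = seed),
            class = "synth_config")
}

synth_genes <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

#' Generate a complete interaction-type tree
#'
#' A complete tree of the configured depth and branching factor
#' (`1 + branching + ... + branching^depth` terms). Directedness is
#' assigned to a seeded random subset of `ceiling(frac_directed * n_leaves)`
#' leaves; internal terms are undirected.
#'
#' @param cfg a `synth_config`.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return an `interaction_ontology`.
#' @export
make_ontology <- function(cfg = synth_config(), seed = cfg$seed) {
  all_ids <- "root"
  parent <- NA_character_
  level <- "root"
  for (d in seq_len(cfg$depth)) {
    kids <- unlist(lapply(level, function(p) {
      pre <- if (p == "root") "" else paste0(p, ".")
      paste0(pre, "t", seq_len(cfg$branching))
    }))
    parent <- c(parent, rep(level, each = cfg$branching))
    all_ids <- c(all_ids, kids)
    level <- kids
  }
  terms <- data.frame(id = all_ids, parent = parent, directed = FALSE,
                      name = paste("interaction type", all_ids),
                      stringsAsFactors = FALSE)
  o <- interaction_ontology(terms)
  leaves <- leaf_terms(o)
  n_dir <- ceiling(cfg$frac_directed * length(leaves))
  if (n_dir > 0) {
    dir_leaves <- with_seed(seed, sample(leaves, n_dir))
    terms$directed[terms$id %in% dir_leaves] <- TRUE
    o <- interaction_ontology(terms)
  }
  o
}

#' Plant hierarchy-consistent labels
#'
#' Leaf positives are drawn independently per gene pair at `pos_rate`
#' (directed leaves receive a random orientation per selected pair), then
#' propagated to all ancestors; per-term negatives are sampled to match
#' the positive count, so the result is a ready gold standard that is
#' hierarchy-consistent by construction.
#'
#' @param o an `interaction_ontology` (typically from [make_ontology()]).
#' @param cfg a `synth_config`.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return named list of `pair_label_set`s, one per term.
#' @export
plant_labels <- function(o, cfg = synth_config(), seed = cfg$seed) {
  genes <- synth_genes(cfg)
  n_pairs <- cfg$n_genes * (cfg$n_genes - 1) / 2
  leaves <- leaf_terms(o)
  raw <- with_seed(seed, {
    out <- list()
    for (leaf in leaves) {
      n_pos <- stats::rbinom(1, n_pairs, cfg$pos_rate)
      if (n_pos == 0L) {
        out[[leaf]] <- new_pairs()
        next
      }
      idx <- sample(n_pairs, n_pos)
      # row-major upper-triangle index -> (i, j)
      cum <- c(0, cumsum((cfg$n_genes - 1):1))
      i <- findInterval(idx - 1, cum)
      j <- i + (idx - cum[i])
      p <- new_pairs(genes[i], genes[j])
      if (is_directed_term(o, leaf)) {
        fl <- stats::runif(n_pos) < 0.5
        p[fl, ] <- new_pairs(p$b[fl], p$a[fl])
      }
      out[[leaf]] <- p
    }
    out
  })
  pos <- propagate_positives(o, raw)
  out <- list()
  for (t in o$terms$id) {
    directed <- is_directed_term(o, t)
    neg <- sample_negatives(pos[[t]], genes, nrow(pos[[t]]),
                            seed = seed + 7L * match(t, o$terms$id),
                            directed = directed)
    out[[t]] <- pair_label_set(t, pos[[t]], neg, directed)
  }
  out
}

#' Synthetic per-term feature model
#'
#' Every term owns `n_informative` feature columns on which its positive
#' pairs are shifted by that term's `delta` (undirected terms: a symmetric
#' shift; directed terms: an antisymmetric shift, so the correct
#' orientation scores `+delta` and the flipped orientation `-delta`); all
#' remaining columns are pure noise shared across terms. Values are
#' generated once per canonical gene pair, so both orientations of a pair
#' are mutually consistent.
#'
#' @param labels planted labels from [plant_labels()].
#' @param cfg a `synth_config`.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return object of class `synth_feature_model`; realize per-term tables
#'   with [synth_features()].
#' @export
make_features <- function(labels, cfg = synth_config(), seed = cfg$seed) {
  terms <- names(labels)
  univ <- dedup_pairs(canonicalize_pairs(do.call(rbind, lapply(labels, function(ls) {
    rbind(ls$positives, ls$negatives)
  }))))
  rownames(univ) <- NULL
  ukeys <- pair_key(univ$a, univ$b)
  deltas <- stats::setNames(rep(cfg$delta, length.out = length(terms)), terms)
  values <- with_seed(seed, {
    cols <- list()
    for (t in terms) {
      ls <- labels[[t]]
      pos_k <- pair_key(ls$positives$a, ls$positives$b)
      if (ls$directed) {
        sgn <- ifelse(ukeys %in% pos_k, 1,
                      ifelse(pair_key(univ$b, univ$a) %in% pos_k, -1, 0))
      } else {
        sgn <- as.numeric(ukeys %in% pos_k)
      }
      m <- matrix(stats::rnorm(nrow(univ) * cfg$n_informative,
                               sd = cfg$noise_sd),
                  nrow = nrow(univ)) + sgn * deltas[t]
      colnames(m) <- paste0(t, ".sig", seq_len(cfg$n_informative))
      cols[[t]] <- m
    }
    noise <- matrix(stats::rnorm(nrow(univ) * cfg$n_noise,
                                 sd = cfg$noise_sd), nrow = nrow(univ))
    if (cfg$n_noise > 0) colnames(noise) <- paste0("noise", seq_len(cfg$n_noise))
    list(cols = cols, noise = noise)
  })
  directed <- vapply(labels, `[[`, TRUE, "directed")
  structure(list(universe = univ, keys = ukeys, values = values,
                 terms = terms, directed = directed, delta = deltas,
                 cfg = cfg),
            class = "synth_feature_model")
}

#' @rdname make_features
#' @param fm a `synth_feature_model`.
#' @param pairs data.frame of (possibly ordered) gene pairs; every pair
#'   must appear (in canonical orientation) in the model's universe.
#' @param term term id whose feature table to realize.
#' @return `synth_features()` returns a `feature_table` with the term's
#'   informative columns plus the shared noise columns; for a directed
#'   term, querying the flipped orientation negates the informative
#'   columns.
#' @export
synth_features <- function(fm, pairs, term) {
  stopifnot(inherits(fm, "synth_feature_model"), term %in% fm$terms)
  canon <- canonicalize_pairs(new_pairs(pairs$a, pairs$b))
  idx <- match(pair_key(canon$a, canon$b), fm$keys)
  if (anyNA(idx)) {
    miss <- pairs[is.na(idx), , drop = FALSE]
    stop(sprintf("%d pair(s) outside the synthetic universe (e.g. %s-%s)",
                 sum(is.na(idx)), miss$a[1], miss$b[1]))
  }
  inf <- fm$values$cols[[term]][idx, , drop = FALSE]
  if (fm$directed[[term]]) {
    flipped <- pairs$a > pairs$b
    inf[flipped, ] <- -inf[flipped, , drop = FALSE]
  }
  vals <- cbind(inf, fm$values$noise[idx, , drop = FALSE])
  feature_table(new_pairs(pairs$a, pairs$b), vals,
                rep("expression", ncol(vals)))
}

#' Mock expression compendium with missingness
#'
#' Source-tagged synthesis for the feature-module tests: genes x
#' conditions Gaussian intensities in `n_datasets` blocks with
#' `missing_rate` of entries masked.
#'
#' @param cfg a `synth_config`.
#' @param n_conditions number of conditions.
#' @param n_datasets number of dataset-of-origin blocks.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return an `expression_compendium`.
#' @export
make_expression <- function(cfg = synth_config(), n_conditions = 20,
                            n_datasets = 2, seed = cfg$seed) {
  genes <- synth_genes(cfg)
  with_seed(seed, {
    v <- matrix(stats::rnorm(cfg$n_genes * n_conditions), cfg$n_genes,
                dimnames = list(genes, paste0("c", seq_len(n_conditions))))
    if (cfg$missing_rate > 0) {
      v[stats::runif(length(v)) < cfg$missing_rate] <- NA
    }
    expression_compendium(v, dataset = paste0(
      "d", rep_len(seq_len(n_datasets), n_conditions)))
  })
}
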
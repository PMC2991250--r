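#' Binary interaction networks
#'
#' Continuously weighted interactomes (posterior edge probabilities) are
#' converted to binary networks by keeping edges whose weight strictly
#' exceeds `mean + k_sd * sd` of the edge weights (the paper-scale setting
#' retains roughly the top 1% of edges).
#'
#' @param weights either a data.frame with columns `a`, `b`, `weight`, or a
#'   `posterior_table` together with `term`.
#' @param k_sd threshold in standard deviations above the mean (default 5;
#'   3 is the common alternative).
#' @param term term id selecting a `posterior_table` column; also recorded
#'   as the network's source term.
#' @param directed logical; whether edges are ordered.
#' @return object of class `binary_network`: `nodes`, `edges` (data.frame
#'   `a`, `b`), `directed`, `term`, `threshold`, `retained_fraction`.
#' @export
binarize <- function(weights, k_sd = 5, term = NA_character_,
                     directed = FALSE) {
  if (inherits(weights, "posterior_table")) {
    if (is.na(term)) stop("`term` is required with a posterior table")
    weights <- data.frame(a = weights$pairs$a, b = weights$pairs$b,
                          weight = weights$posterior[, term],
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("a", "b", "weight") %in% names(weights)))
  w <- weights$weight
  if (length(w) < 2) stop("need at least two weighted edges")
  m <- mean(w)
  s <- stats::sd(w)
  nodes <- sort(unique(c(weights$a, weights$b)))
  if (!is.finite(s) || s == 0) {
    warning("zero weight variance; no edges retained")
    keep <- rep(FALSE, length(w))
  } else {
    keep <- w > m + k_sd * s
  }
  edges <- new_pairs(weights$a[keep], weights$b[keep])
  if (!directed) edges <- dedup_pairs(canonicalize_pairs(edges))
  structure(list(nodes = nodes, edges = edges, directed = directed,
                 term = term, threshold = m + k_sd * s,
                 retained_fraction = sum(keep) / length(w)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary network%s: %d nodes, %d %s edges (%.2f%% of weighted edges retained)\n",
              if (is.na(x$term)) "" else paste0(" '", x$term, "'"),
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected",
              100 * x$retained_fraction))
  invisible(x)
}

#' @rdname binarize
#' @param n a `binary_network`.
#' @export
as_igraph <- function(n) {
  stopifnot(inherits(n, "binary_network"))
  igraph::graph_from_data_frame(n$edges, directed = n$directed,
                                vertices = n$nodes)
}

network_degrees <- function(n, mode = c("all", "in", "out")) {
  mode <- match.arg(mode)
  deg <- stats::setNames(rep(0L, length(n$nodes)), n$nodes)
  ends <- switch(mode,
                 all = c(n$edges$a, n$edges$b),
                 `in` = n$edges$b,
                 out = n$edges$a)
  tab <- table(ends)
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Degree histogram and scale-free diagnostic
#'
#' Degree histogram (in/out separately for directed networks) plus the
#' least-squares slope of log10(count) against log10(degree) over degrees
#' with nonzero count — scale-free topologies show an approximately linear
#' decay. The slope is `NA` when fewer than two distinct degrees exist.
#'
#' @param n a nonempty `binary_network`.
#' @return for undirected networks a list with `histogram` (data.frame
#'   `degree`, `count`) and `slope`; for directed networks a list with
#'   components `in_`, `out` and `all` of that shape.
#' @export
degree_stats <- function(n) {
  stopifnot(inherits(n, "binary_network"))
  if (nrow(n$edges) == 0L) stop("empty network")
  one <- function(mode) {
    deg <- network_degrees(n, mode)
    deg <- deg[deg > 0]
    tab <- table(deg)
    hist <- data.frame(degree = as.integer(names(tab)),
                       count = as.integer(tab))
    slope <- NA_real_
    if (nrow(hist) >= 2L) {
      fit <- stats::lm(log10(count) ~ log10(degree), data = hist)
      slope <- unname(stats::coef(fit)[2])
    }
    list(histogram = hist, slope = slope)
  }
  if (n$directed) {
    list(in_ = one("in"), out = one("out"), all = one("all"))
  } else {
    one("all")
  }
}

#' Hub-overlap matrix across interactomes
#'
#' For each ordered pair of networks, the conditional probability that a
#' gene in the top-`quantile` degree set of one network also sits in the
#' top set of another: `P[g in Q(N1) | g in Q(N2)]`. Directed networks
#' contribute separate in-degree and out-degree entries. Hub sets are the
#' top `ceiling(quantile * n)` nodes by degree over the shared node
#' universe, ties broken by gene id for determinism.
#'
#' @param networks named list of `binary_network`s over a shared node
#'   universe.
#' @param quantile top-degree proportion defining hubs (default 0.05).
#' @return object of class `hub_overlap_matrix`: list with `labels`,
#'   `values` (matrix, entry (i, j) = P[g in Q_i | g in Q_j]), `order`
#'   (average-linkage clustering order on distance 1 - overlap) and
#'   `hub_sets`.
#' @export
hub_overlap <- function(networks, quantile = 0.05) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  if (is.null(names(networks))) {
    names(networks) <- vapply(networks, function(n) n$term, "")
  }
  universe <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
  n_top <- ceiling(quantile * length(universe))
  hub_sets <- list()
  for (nm in names(networks)) {
    net <- networks[[nm]]
    modes <- if (net$directed) c("in", "out") else "all"
    for (md in modes) {
      deg <- stats::setNames(rep(0L, length(universe)), universe)
      d <- network_degrees(net, md)
      deg[names(d)] <- d
      top <- universe[order(-deg, universe)][seq_len(n_top)]
      label <- if (net$directed) paste0(nm, ":", md) else nm
      hub_sets[[label]] <- top
    }
  }
  labels <- names(hub_sets)
  m <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in labels) {
    for (j in labels) {
      m[i, j] <- length(intersect(hub_sets[[i]], hub_sets[[j]])) /
        length(hub_sets[[j]])
    }
  }
  ord <- seq_along(labels)
  if (length(labels) > 2L) {
    sym <- 1 - (m + t(m)) / 2
    ord <- stats::hclust(stats::as.dist(sym), method = "average")$order
  }
  structure(list(labels = labels, values = m, order = ord,
                 hub_sets = hub_sets, quantile = quantile),
            class = "hub_overlap_matrix")
}

#' @export
print.hub_overlap_matrix <- function(x, ...) {
  cat(sprintf("hub overlap matrix: %d networks, top %.0f%% hubs\n",
              length(x$labels), 100 * x$quantile))
  print(round(x$values, 3))
  invisible(x)
}

#' Read / write edge-list TSV networks
#'
#' Two or three tab-separated columns: `a b` or `a b weight`.
#'
#' @param path file path.
#' @param directed logical.
#' @return `read_edge_list()` returns a data.frame (`a`, `b`[, `weight`]).
#' @export
read_edge_list <- function(path, directed = FALSE) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         stringsAsFactors = FALSE)
  names(d) <- c("a", "b", "weight")[seq_len(ncol(d))]
  d$a <- as.character(d$a)
  d$b <- as.character(d$b)
  d
}

#' @rdname read_edge_list
#' @param edges data.frame with columns `a`, `b` and optionally `weight`,
#'   or a `binary_network`.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "binary_network")) edges <- edges$edges
  cols <- intersect(c("a", "b", "weight"), names(edges))
  utils::write.table(edges[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
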
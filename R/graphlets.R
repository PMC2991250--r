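#' Graphlet catalog: the 30 connected 2-5-node graphs and their 73 orbits
#'
#' Graphlets are the non-isomorphic connected undirected graphs on 2-5
#' nodes; an orbit is an automorphism-equivalence class of node positions
#' within a graphlet. The catalog is generated deterministically (graphlets
#' ordered by size, then edge count, then canonical adjacency code; orbits
#' within a graphlet by node degree, then marked canonical code), which
#' reproduces the conventional numbering for the small cases: orbit 0 is
#' the edge end (degree), orbits 1/2 the 3-path ends/middle, orbit 3 the
#' triangle.
#'
#' @return A list with `graphlets` (data.frame: `graphlet`, `k`, `n_edges`,
#'   `code`), `orbits` (data.frame: `orbit` (0-based), `graphlet`, `k`,
#'   `degree`, `marked_code`), `n_orbits` (73) and `lookup` (per-size
#'   marked-code to orbit tables used by [orbit_counts()]).
#' @export
graphlet_catalog <- function() {
  if (is.null(.ow_env$catalog)) .ow_env$catalog <- build_graphlet_catalog()
  .ow_env$catalog
}

.ow_env <- new.env(parent = emptyenv())

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# bit index (0-based) of pair (i, j), 1-based i < j, in a k-node code;
# mirrors pair_bit() in src/orbits.cpp
pair_bit_r <- function(i, j, k) {
  i0 <- i - 1L
  j0 <- j - 1L
  i0 * k - i0 * (i0 + 1L) / 2L + (j0 - i0 - 1L)
}

adj_code <- function(adj, ord) {
  k <- length(ord)
  code <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (adj[ord[i], ord[j]]) {
        code <- code + bitwShiftL(1L, pair_bit_r(i, j, k))
      }
    }
  }
  code
}

canonical_code <- function(adj, perms) {
  min(vapply(perms, function(p) adj_code(adj, p), 0L))
}

# canonical code with vertex v forced into the first (marked) position
marked_code <- function(adj, v, perms_rest) {
  others <- setdiff(seq_len(nrow(adj)), v)
  if (!length(others)) return(0L)
  min(vapply(perms_rest, function(p) adj_code(adj, c(v, others[p])), 0L))
}

is_connected_adj <- function(adj) {
  k <- nrow(adj)
  seen <- rep(FALSE, k)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

build_graphlet_catalog <- function() {
  graphlets <- list()
  orbits <- list()
  lookup <- list()
  g_id <- 0L
  orbit_id <- 0L
  for (k in 2:5) {
    perms_k <- all_perms(seq_len(k))
    perms_rest <- all_perms(seq_len(k - 1L))
    np <- k * (k - 1L) / 2L
    pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    seen <- integer(0)
    classes <- list()
    for (mask in seq_len(bitwShiftL(1L, np) - 1L)) {
      adj <- matrix(FALSE, k, k)
      for (b in seq_len(np)) {
        if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) {
          adj[pairs[b, 1], pairs[b, 2]] <- TRUE
          adj[pairs[b, 2], pairs[b, 1]] <- TRUE
        }
      }
      if (!is_connected_adj(adj)) next
      code <- canonical_code(adj, perms_k)
      if (code %in% seen) next
      seen <- c(seen, code)
      classes[[length(classes) + 1L]] <- list(code = code, adj = adj,
                                              n_edges = as.integer(sum(adj) / 2))
    }
    ord <- order(vapply(classes, `[[`, 0L, "n_edges"),
                 vapply(classes, `[[`, 0L, "code"))
    classes <- classes[ord]
    codes_k <- integer(0)
    orbit_k <- integer(0)
    for (cl in classes) {
      adj <- cl$adj
      # automorphisms: permutations preserving adjacency
      autos <- Filter(function(p) {
        identical(adj[p, p], adj)
      }, perms_k)
      # orbit partition: closure of v -> p[v] over automorphisms
      rep_of <- seq_len(k)
      for (p in autos) {
        for (v in seq_len(k)) {
          r1 <- min(rep_of[rep_of == rep_of[v]])
          r2 <- min(rep_of[rep_of == rep_of[p[v]]])
          r <- min(r1, r2)
          rep_of[rep_of %in% c(r1, r2)] <- r
        }
      }
      parts <- split(seq_len(k), rep_of)
      deg <- rowSums(adj)
      mcodes <- vapply(seq_len(k), function(v) marked_code(adj, v, perms_rest), 0L)
      parts <- parts[order(vapply(parts, function(vs) deg[vs[1]], 0),
                           vapply(parts, function(vs) mcodes[vs[1]], 0L))]
      for (vs in parts) {
        orbits[[length(orbits) + 1L]] <- data.frame(
          orbit = orbit_id, graphlet = g_id, k = k,
          degree = deg[vs[1]], marked_code = mcodes[vs[1]], size = length(vs))
        codes_k <- c(codes_k, mcodes[vs[1]])
        orbit_k <- c(orbit_k, orbit_id)
        orbit_id <- orbit_id + 1L
      }
      graphlets[[length(graphlets) + 1L]] <- data.frame(
        graphlet = g_id, k = k, n_edges = cl$n_edges, code = cl$code)
      g_id <- g_id + 1L
    }
    lookup[[k - 1L]] <- list(codes = codes_k, orbits = orbit_k)
  }
  list(graphlets = do.call(rbind, graphlets),
       orbits = do.call(rbind, orbits),
       n_orbits = orbit_id,
       lookup = lookup)
}

#' Graphlet orbit counts per node
#'
#' For every node, counts its incidences in each of the 73 automorphism
#' orbits of the 30 connected 2-5-node graphlets, by exact enumeration of
#' connected induced subgraphs (ESU). Orbit 0 equals the node degree.
#'
#' @param n a `binary_network` (treated as undirected; directions dropped),
#'   or an edge data.frame with columns `a`, `b` plus a `nodes` argument.
#' @param nodes optional character vector of node ids (defaults to the
#'   network's nodes).
#' @param max_nodes,max_edges refusal caps for exhaustive enumeration
#'   (defaults 5000 / 50000); larger graphs should be down-sampled first.
#' @return object of class `orbit_table`: integer matrix nodes x 73
#'   (columns `O0`..`O72`).
#' @export
orbit_counts <- function(n, nodes = NULL, max_nodes = 5000,
                         max_edges = 50000) {
  if (inherits(n, "binary_network")) {
    nodes <- nodes %||% n$nodes
    edges <- n$edges
  } else {
    edges <- n
    if (is.null(nodes)) nodes <- sort(unique(c(edges$a, edges$b)))
  }
  edges <- dedup_pairs(canonicalize_pairs(new_pairs(edges$a, edges$b)))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  if (length(nodes) > max_nodes || nrow(edges) > max_edges) {
    stop(sprintf(
      "graph too large for exhaustive orbit enumeration (%d nodes, %d edges; caps %d / %d); down-sample or raise the caps",
      length(nodes), nrow(edges), max_nodes, max_edges))
  }
  cat_ <- graphlet_catalog()
  em <- cbind(match(edges$a, nodes), match(edges$b, nodes)) - 1L
  if (anyNA(em)) stop("edge endpoints missing from `nodes`")
  storage.mode(em) <- "integer"
  counts <- orbit_counts_cpp(length(nodes), em, cat_$lookup,
                             cat_$n_orbits, 5L)
  dimnames(counts) <- list(nodes, paste0("O", seq_len(cat_$n_orbits) - 1L))
  structure(counts, class = c("orbit_table", class(counts)))
}

#' Graphlet-degree-distribution (GDD) agreement
#'
#' For each orbit j, the distribution over k >= 1 of the number of nodes
#' touching k graphlets at that orbit is scaled by 1/k and normalized to
#' sum one; the per-orbit distance between two networks is the Euclidean
#' distance of the normalized distributions divided by sqrt(2), and the
#' per-orbit agreement is one minus that distance. The GDD agreement is
#' the average over the 73 orbits (arithmetic by default). An orbit empty
#' in both networks agrees perfectly; an orbit empty in exactly one is
#' compared against the zero distribution.
#'
#' @param a,b `orbit_table`s (from [orbit_counts()]).
#' @param average `"arithmetic"` (default) or `"geometric"` averaging of
#'   per-orbit agreements.
#' @return a single agreement value in `[0, 1]`; attribute `per_orbit`
#'   holds the 73 per-orbit agreements.
#' @export
gdd_agreement <- function(a, b, average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  stopifnot(ncol(a) == ncol(b))
  norm_dist <- function(counts) {
    counts <- counts[counts >= 1]
    if (!length(counts)) return(numeric(0))
    tab <- table(counts)
    k <- as.numeric(names(tab))
    s <- as.numeric(tab) / k
    stats::setNames(s / sum(s), names(tab))
  }
  per_orbit <- vapply(seq_len(ncol(a)), function(j) {
    ta <- norm_dist(a[, j])
    tb <- norm_dist(b[, j])
    if (!length(ta) && !length(tb)) return(1)
    ks <- union(names(ta), names(tb))
    va <- ifelse(ks %in% names(ta), ta[ks], 0)
    vb <- ifelse(ks %in% names(tb), tb[ks], 0)
    1 - sqrt(sum((va - vb)^2)) / sqrt(2)
  }, 0)
  agg <- if (average == "arithmetic") mean(per_orbit)
         else exp(mean(log(pmax(per_orbit, .Machine$double.xmin))))
  structure(agg, per_orbit = per_orbit)
}
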
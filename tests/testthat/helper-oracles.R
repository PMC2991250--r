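# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: enumeration, direct counting and closed forms.

new_pairs_helper <- function() {
  data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
}

# --- random rooted trees ----------------------------------------------------

random_tree_terms <- function(n_terms, frac_directed = 0, seed = NULL) {
  draw <- function() {
    parent <- c(NA_character_,
                vapply(seq_len(n_terms - 1L) + 1L, function(i) {
                  paste0("T", sample.int(i - 1L, 1))
                }, ""))
    data.frame(id = paste0("T", seq_len(n_terms)), parent = parent,
               directed = stats::runif(n_terms) < frac_directed,
               name = paste("term", seq_len(n_terms)),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else with_seed_helper(seed, draw())
}

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# --- BFS depths (oracle for ancestors) --------------------------------------

bfs_depths <- function(terms) {
  root <- terms$id[is.na(terms$parent)]
  depth <- stats::setNames(rep(NA_integer_, nrow(terms)), terms$id)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    kids <- terms$id[!is.na(terms$parent) & terms$parent %in% frontier]
    depth[kids] <- depth[terms$parent[match(kids, terms$id)]] + 1L
    frontier <- kids
  }
  depth
}

# --- brute-force AUC (concordant-pair counting, ties = 1/2) -----------------

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# --- exhaustive posterior enumeration over all 2^n latent assignments -------

enum_posteriors <- function(o, q, L0, L1) {
  ids <- o$terms$id
  nt <- length(ids)
  configs <- as.matrix(expand.grid(rep(list(0:1), nt)))
  colnames(configs) <- ids
  jp <- rep(1, nrow(configs))
  for (t in ids) {
    ch <- o$children[[t]]
    pr1 <- if (length(ch)) {
      ifelse(rowSums(configs[, ch, drop = FALSE]) > 0, 1, q[[t]])
    } else {
      rep(q[[t]], nrow(configs))
    }
    on <- configs[, t] == 1
    jp <- jp * ifelse(on, pr1 * L1[[t]], (1 - pr1) * L0[[t]])
  }
  vapply(ids, function(t) sum(jp[configs[, t] == 1]) / sum(jp), 0)
}

# Build a hierarchical_model with prescribed structural probabilities and
# two-bin observation CPTs realizing arbitrary likelihood pairs; a score of
# -0.5 lands in bin 1, +0.5 in bin 2.
toy_model <- function(o, q, L0, L1) {
  ids <- o$terms$id
  disc <- lapply(ids, function(t) {
    structure(list(term = t, mean = 0, sd = 1, n_bins = 2L,
                   edges = c(-1, 0, 1)),
              class = "discretization_scheme")
  })
  names(disc) <- ids
  obs <- lapply(ids, function(t) {
    p <- cbind("0" = c(L0[[t]], 1 - L0[[t]]), "1" = c(L1[[t]], 1 - L1[[t]]))
    structure(list(term = t, p = p, pseudocount = 0),
              class = "observation_cpt")
  })
  names(obs) <- ids
  st <- lapply(ids, function(t) {
    structure(list(term = t, children = o$children[[t]], q = q[[t]],
                   n = 10L),
              class = "structural_cpt")
  })
  names(st) <- ids
  hierarchical_model(o, disc, obs, st)
}

# --- graphlet orbit oracle --------------------------------------------------
# Exhaustive combn() subset enumeration; connectivity by matrix powers;
# orbit identification by VF2 marked-graph isomorphism (igraph) against the
# catalog's decoded representatives. Independent of the package's ESU
# enumeration and canonical-code classification.

decode_graphlet_adj <- function(code, k) {
  adj <- matrix(FALSE, k, k)
  b <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (bitwAnd(code, bitwShiftL(1L, b)) != 0L) {
        adj[i, j] <- TRUE
        adj[j, i] <- TRUE
      }
      b <- b + 1L
    }
  }
  adj
}

# marked reference graphs per orbit: list of (k, degree, igraph with colors)
orbit_references <- function() {
  cat_ <- graphlet_catalog()
  refs <- vector("list", cat_$n_orbits)
  for (r in seq_len(nrow(cat_$orbits))) {
    row <- cat_$orbits[r, ]
    g_adj <- decode_graphlet_adj(
      cat_$graphlets$code[cat_$graphlets$graphlet == row$graphlet], row$k)
    # find a vertex of this orbit: same marked code
    pr <- perms_helper(row$k - 1L)
    v <- which(vapply(seq_len(row$k), function(v) {
      marked_code_helper(g_adj, v, pr)
    }, 0L) == row$marked_code)[1]
    g <- igraph::graph_from_adjacency_matrix(g_adj, mode = "undirected")
    col <- rep(1L, row$k)
    col[v] <- 2L
    refs[[row$orbit + 1L]] <- list(k = row$k, degree = row$degree,
                                   graph = g, colors = col)
  }
  refs
}

perms_helper <- function(m) {
  if (m <= 0L) return(list(integer(0)))
  if (m == 1L) return(list(1L))
  out <- list()
  for (p in perms_helper(m - 1L)) {
    for (pos in seq_len(m)) {
      out[[length(out) + 1L]] <- append(p, m, after = pos - 1L)
    }
  }
  out
}

marked_code_helper <- function(adj, v, perms_rest) {
  k <- nrow(adj)
  others <- setdiff(seq_len(k), v)
  if (!length(others)) return(0L)
  best <- NULL
  for (p in perms_rest) {
    ord <- c(v, others[p])
    code <- 0L
    b <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (adj[ord[i], ord[j]]) code <- code + bitwShiftL(1L, b)
        b <- b + 1L
      }
    }
    if (is.null(best) || code < best) best <- code
  }
  best
}

oracle_orbit_counts <- function(adj, refs) {
  n <- nrow(adj)
  counts <- matrix(0L, n, length(refs))
  for (k in 2:min(5, n)) {
    subsets <- utils::combn(n, k)
    # vectorized edge-count prefilter: connected needs >= k - 1 edges
    ec <- rep(0L, ncol(subsets))
    for (r1 in seq_len(k - 1)) {
      for (r2 in (r1 + 1):k) {
        ec <- ec + adj[cbind(subsets[r1, ], subsets[r2, ])]
      }
    }
    for (s in which(ec >= k - 1)) {
      vs <- subsets[, s]
      sub <- adj[vs, vs, drop = FALSE]
      reach <- diag(k) + sub
      for (step in seq_len(k - 2)) reach <- reach %*% (diag(k) + sub)
      if (any(reach[1, ] == 0)) next
      deg <- rowSums(sub)
      g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
      for (vi in seq_len(k)) {
        col <- rep(1L, k)
        col[vi] <- 2L
        hit <- NA_integer_
        for (oid in seq_along(refs)) {
          ref <- refs[[oid]]
          if (ref$k != k || ref$degree != deg[vi]) next
          if (igraph::isomorphic(g, ref$graph, method = "vf2",
                                 vertex.color1 = col,
                                 vertex.color2 = ref$colors)) {
            hit <- oid
            break
          }
        }
        stopifnot(!is.na(hit))
        counts[vs[vi], hit] <- counts[vs[vi], hit] + 1L
      }
    }
  }
  counts
}

random_gnp_adj <- function(n, p, seed) {
  with_seed_helper(seed, {
    adj <- matrix(FALSE, n, n)
    up <- which(upper.tri(adj))
    on <- up[stats::runif(length(up)) < p]
    adj[on] <- TRUE
    adj | t(adj)
  })
}

adj_to_edges <- function(adj, nodes = NULL) {
  if (is.null(nodes)) nodes <- sprintf("n%02d", seq_len(nrow(adj)))
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  data.frame(a = nodes[idx[, 1]], b = nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

# --- triad census oracle ----------------------------------------------------
# Classifies each connected node triple by a combinatorial invariant
# (sorted per-node out/in signatures + dyad census); the invariant-to-label
# mapping is established once from single-triad graphs.

triad_invariant <- function(m) {
  # m: 3x3 logical directed adjacency
  mut <- sum(m & t(m)) / 2
  asym <- sum(m & !t(m))
  null <- 3 - mut - asym
  sig <- sort(paste(rowSums(m), colSums(m), sep = "/"))
  paste(mut, asym, null, paste(sig, collapse = ","), sep = "|")
}

triad_class_map <- local({
  map <- NULL
  function() {
    if (!is.null(map)) return(map)
    classes <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                 "111U", "030T", "030C", "201", "120D", "120U", "120C",
                 "210", "300")
    out <- character(0)
    for (bits in 0:63) {
      m <- matrix(FALSE, 3, 3)
      off <- which(diag(3) == 0)
      m[off] <- bitwAnd(bits, bitwShiftL(1L, seq_along(off) - 1L)) != 0L
      inv <- triad_invariant(m)
      if (!inv %in% names(out)) {
        g <- igraph::graph_from_adjacency_matrix(m, mode = "directed")
        cls <- classes[which(igraph::triad_census(g) == 1)]
        out[inv] <- cls
      } else {
        g <- igraph::graph_from_adjacency_matrix(m, mode = "directed")
        cls <- classes[which(igraph::triad_census(g) == 1)]
        stopifnot(identical(out[[inv]], cls))  # invariant must be complete
      }
    }
    map <<- out
    map
  }
})

oracle_triad_census <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  m <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  m[cbind(net$edges$a, net$edges$b)] <- TRUE
  classes <- c("021D", "021U", "021C", "111D", "111U", "030T", "030C",
               "201", "120D", "120U", "120C", "210", "300")
  counts <- stats::setNames(rep(0L, 13), classes)
  cmap <- triad_class_map()
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    sub <- m[tri, tri]
    und <- sub | t(sub)
    reach <- (diag(3) + und) %*% (diag(3) + und)
    if (any(reach[1, ] == 0)) next
    cls <- cmap[[triad_invariant(sub)]]
    counts[cls] <- counts[cls] + 1L
  }
  counts
}
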
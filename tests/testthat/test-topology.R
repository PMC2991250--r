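test_that("binarization keeps strictly above-threshold edges and records the fraction", {
  w <- data.frame(a = c("a", "a", "b", "c"), b = c("b", "c", "c", "d"),
                  weight = c(0, 0, 0, 10))
  net <- binarize(w, k_sd = 1)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$a, "c")
  expect_equal(net$retained_fraction, 0.25)

  expect_warning(net0 <- binarize(data.frame(a = c("a", "b"), b = c("b", "c"),
                                             weight = c(1, 1))),
                 "zero weight variance")
  expect_identical(nrow(net0$edges), 0L)

  # retained fraction is nonincreasing in k_sd
  with_seed_helper(6, {
    ww <- data.frame(a = sprintf("a%d", 1:200), b = sprintf("b%d", 1:200),
                     weight = rexp(200))
  })
  fr <- sapply(c(0, 0.5, 1, 2, 3, 5), function(k) {
    binarize(ww, k_sd = k)$retained_fraction
  })
  expect_true(all(diff(fr) <= 0))
})

test_that("degree statistics recover star structure and flag degenerate fits", {
  star <- structure(list(
    nodes = c("hub", sprintf("s%d", 1:6)),
    edges = data.frame(a = "hub", b = sprintf("s%d", 1:6),
                       stringsAsFactors = FALSE),
    directed = FALSE, term = NA_character_, threshold = NA_real_,
    retained_fraction = NA_real_), class = "binary_network")
  ds <- degree_stats(star)
  expect_equal(ds$histogram$count[ds$histogram$degree == 1], 6)
  expect_equal(ds$histogram$count[ds$histogram$degree == 6], 1)

  ring <- structure(list(
    nodes = sprintf("r%d", 1:5),
    edges = data.frame(a = sprintf("r%d", 1:5),
                       b = sprintf("r%d", c(2:5, 1)),
                       stringsAsFactors = FALSE),
    directed = FALSE, term = NA_character_, threshold = NA_real_,
    retained_fraction = NA_real_), class = "binary_network")
  expect_true(is.na(degree_stats(ring)$slope))  # 2-regular: single bin

  # preferential-attachment-like network: steep negative slope
  with_seed_helper(8, {
    g <- igraph::sample_pa(400, m = 2, directed = FALSE)
  })
  el <- igraph::as_edgelist(g)
  pa <- structure(list(nodes = as.character(1:400),
                       edges = data.frame(a = as.character(el[, 1]),
                                          b = as.character(el[, 2]),
                                          stringsAsFactors = FALSE),
                       directed = FALSE, term = NA_character_,
                       threshold = NA_real_, retained_fraction = NA_real_),
                  class = "binary_network")
  expect_lt(degree_stats(pa)$slope, -1)
})

test_that("hub overlap matches explicit set computation and handles directed networks", {
  mknet <- function(edges, directed = FALSE, nodes) {
    structure(list(nodes = nodes, edges = edges, directed = directed,
                   term = NA_character_, threshold = NA_real_,
                   retained_fraction = NA_real_), class = "binary_network")
  }
  nodes <- sprintf("g%02d", 1:40)
  with_seed_helper(9, {
    nets <- lapply(1:3, function(i) {
      i_ <- sample(40, 60, replace = TRUE)
      j_ <- sample(39, 60, replace = TRUE)
      j_ <- ifelse(j_ >= i_, j_ + 1, j_)
      mknet(unique(data.frame(a = pmin(nodes[i_], nodes[j_]),
                              b = pmax(nodes[i_], nodes[j_]),
                              stringsAsFactors = FALSE)),
            nodes = nodes)
    })
  })
  names(nets) <- paste0("N", 1:3)
  ho <- hub_overlap(nets, quantile = 0.1)
  expect_equal(unname(diag(ho$values)), rep(1, 3))
  for (i in 1:3) {
    for (j in 1:3) {
      expect_equal(ho$values[i, j],
                   length(intersect(ho$hub_sets[[i]], ho$hub_sets[[j]])) /
                     length(ho$hub_sets[[j]]))
    }
  }

  # directed networks appear as :in and :out variants
  dn <- mknet(data.frame(a = nodes[1:10], b = nodes[11:20],
                         stringsAsFactors = FALSE), directed = TRUE,
              nodes = nodes)
  ho2 <- hub_overlap(list(D = dn, U = nets[[1]]), quantile = 0.1)
  expect_setequal(ho2$labels, c("D:in", "D:out", "U"))

  expect_error(hub_overlap(nets, quantile = 1.2), "quantile")
})

test_that("the graphlet catalog has 30 graphlets and 73 orbits with the small identities", {
  cat_ <- graphlet_catalog()
  expect_identical(nrow(cat_$graphlets), 30L)
  expect_identical(cat_$n_orbits, 73L)
  expect_identical(as.integer(table(cat_$graphlets$k)), c(1L, 2L, 6L, 21L))
  # each graphlet's orbit sizes sum to its node count
  sizes <- tapply(cat_$orbits$size, cat_$orbits$graphlet, sum)
  expect_equal(as.vector(sizes),
               cat_$graphlets$k[order(cat_$graphlets$graphlet)])
  # conventional small numbering: edge, path ends/middle, triangle
  expect_equal(cat_$orbits$degree[1:4], c(1, 1, 2, 2))
  expect_equal(cat_$orbits$graphlet[1:4], c(0, 1, 1, 2))
})

test_that("orbit counts on canonical small graphs match hand expectations", {
  tri <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"))
  oc <- orbit_counts(tri)
  expect_equal(unname(oc[, "O0"]), rep(2, 3))
  expect_equal(unname(oc[, "O3"]), rep(1, 3))
  expect_true(all(oc[, setdiff(colnames(oc), c("O0", "O3"))] == 0))

  p3 <- data.frame(a = c("A", "B"), b = c("B", "C"))
  oc2 <- orbit_counts(p3)
  expect_equal(unname(oc2[c("A", "C"), "O1"]), c(1, 1))
  expect_equal(unname(oc2["B", "O2"]), 1)
})

test_that("orbit counts match exhaustive subset enumeration with VF2 classification", {
  refs <- orbit_references()
  specs <- list(c(n = 9, p = 0.40), c(n = 12, p = 0.30), c(n = 16, p = 0.18))
  for (seed in 1:9) {
    sp <- specs[[(seed %% 3) + 1]]
    adj <- random_gnp_adj(sp[["n"]], sp[["p"]], seed = 100 + seed)
    edges <- adj_to_edges(adj)
    nodes <- sprintf("n%02d", seq_len(nrow(adj)))
    got <- orbit_counts(edges, nodes = nodes)
    want <- oracle_orbit_counts(adj, refs)
    expect_equal(unclass(got), want,
                 ignore_attr = TRUE)
    # orbit-0 column is the degree vector; triangle totals agree with trace
    expect_equal(unname(got[, "O0"]), rowSums(adj) + 0L, ignore_attr = TRUE)
    a_num <- adj * 1
    n_tri <- sum(diag(a_num %*% a_num %*% a_num)) / 6
    expect_equal(sum(got[, "O3"]), 3 * n_tri)
  }
})

test_that("GDD agreement is 1 on identical networks, symmetric and bounded", {
  with_seed_helper(21, {
    adj1 <- random_gnp_adj(15, 0.25, seed = 31)
    adj2 <- random_gnp_adj(15, 0.25, seed = 32)
  })
  o1 <- orbit_counts(adj_to_edges(adj1), nodes = sprintf("n%02d", 1:15))
  o2 <- orbit_counts(adj_to_edges(adj2), nodes = sprintf("n%02d", 1:15))
  expect_equal(as.numeric(gdd_agreement(o1, o1)), 1)
  expect_equal(as.numeric(gdd_agreement(o1, o2)),
               as.numeric(gdd_agreement(o2, o1)))
  g <- as.numeric(gdd_agreement(o1, o2))
  expect_gte(g, 0)
  expect_lte(g, 1)
  expect_true(all(attr(gdd_agreement(o1, o2), "per_orbit") >= 0))

  # hand-checked per-orbit normalization on two tiny graphs: triangle vs 3-path
  ot <- orbit_counts(data.frame(a = c("A", "A", "B"), b = c("B", "C", "C")))
  op <- orbit_counts(data.frame(a = c("A", "B"), b = c("B", "C")))
  per <- attr(gdd_agreement(ot, op), "per_orbit")
  # orbit 0: triangle all nodes degree 2 -> T = {2: 1}; path: two deg-1, one
  # deg-2 -> S = {1: 2, 2: 0.5}, T = {1: 0.8, 2: 0.2}
  d0 <- sqrt(0.8^2 + (1 - 0.2)^2) / sqrt(2)
  expect_equal(per[1], 1 - d0)
  # orbits empty in both networks agree perfectly
  expect_equal(per[10], 1)
})

test_that("geometric averaging is available and agrees at the fixed point", {
  adj <- random_gnp_adj(10, 0.3, seed = 77)
  oc <- orbit_counts(adj_to_edges(adj), nodes = sprintf("n%02d", 1:10))
  expect_equal(as.numeric(gdd_agreement(oc, oc, average = "geometric")), 1)
})

test_that("triad census identifies the canonical FFL and cycle and matches brute force", {
  mknet <- function(a, b, nodes) {
    structure(list(nodes = nodes, edges = data.frame(a = a, b = b,
                                                     stringsAsFactors = FALSE),
                   directed = TRUE, term = NA_character_,
                   threshold = NA_real_, retained_fraction = NA_real_),
              class = "binary_network")
  }
  ffl <- mknet(c("A", "A", "B"), c("B", "C", "C"), c("A", "B", "C"))
  tc <- triad_census(ffl)
  expect_equal(unname(tc["030T"]), 1L)
  expect_equal(sum(tc), 1L)

  cyc <- mknet(c("A", "B", "C"), c("B", "C", "A"), c("A", "B", "C"))
  tc2 <- triad_census(cyc)
  expect_equal(unname(tc2["030C"]), 1L)
  expect_equal(unname(tc2["030T"]), 0L)

  und <- ffl
  und$directed <- FALSE
  expect_error(triad_census(und), "directed")

  for (seed in 1:8) {
    with_seed_helper(seed, {
      n <- sample(6:15, 1)
      nodes <- sprintf("v%02d", 1:n)
      m <- sample(5:40, 1)
      a <- sample(nodes, m, replace = TRUE)
      b <- sample(nodes, m, replace = TRUE)
    })
    keep <- a != b
    ed <- unique(data.frame(a = a[keep], b = b[keep],
                            stringsAsFactors = FALSE))
    net <- mknet(ed$a, ed$b, nodes)
    expect_equal(unname(triad_census(net)), unname(oracle_triad_census(net)))
  }
})

test_that("edge-swap nulls preserve in/out degree sequences bit-exactly", {
  net <- plant_ffl_network(n_nodes = 40, n_background = 80, n_ffl = 10,
                           seed = 5)
  din <- table(factor(net$edges$b, levels = net$nodes))
  dout <- table(factor(net$edges$a, levels = net$nodes))
  for (s in 1:10) {
    null <- edge_swap_null(net, swaps_per_edge = 10, seed = s)
    expect_identical(nrow(null$edges), nrow(net$edges))
    expect_equal(as.integer(table(factor(null$edges$b, levels = net$nodes))),
                 as.integer(din))
    expect_equal(as.integer(table(factor(null$edges$a, levels = net$nodes))),
                 as.integer(dout))
    expect_false(any(null$edges$a == null$edges$b))
    expect_false(any(duplicated(paste(null$edges$a, null$edges$b))))
  }
  # nulls differ from the original network with overwhelming probability
  null <- edge_swap_null(net, swaps_per_edge = 10, seed = 1)
  expect_false(identical(
    sort(paste(null$edges$a, null$edges$b)),
    sort(paste(net$edges$a, net$edges$b))))
})

test_that("planted feed-forward loops are detected as enriched", {
  net <- plant_ffl_network(seed = 2)
  enr <- motif_enrichment(net, n_random = 100, seed = 11)
  ffl <- enr[enr$class == "030T", ]
  expect_gt(ffl$z, 2)
  expect_lt(ffl$p_emp, 0.05)
  # absent classes: p = 1 and flagged degenerate when variance is zero
  absent <- enr[enr$real == 0 & enr$null_mean == 0, ]
  if (nrow(absent)) {
    expect_true(all(absent$p_emp == 1))
    expect_true(all(is.na(absent$z)))
  }
})

test_that("sampled triad census approximates the exhaustive census", {
  net <- plant_ffl_network(n_nodes = 50, n_background = 150, n_ffl = 20,
                           seed = 3)
  full <- triad_census(net)
  est <- triad_census_sampled(net, probs = c(1, 1, 1), seed = 1)
  expect_equal(unname(est), unname(as.numeric(full)))
  est2 <- triad_census_sampled(net, probs = c(0.6, 0.5, 0.4), seed = 1)
  # unbiased estimator: within a loose factor on the dominant classes
  big <- full[full > 20]
  expect_true(all(abs(est2[names(big)] - big) / big < 0.75))
})

test_that("edge lists round trip through the TSV reader and writer", {
  f <- withr::local_tempfile(fileext = ".tsv")
  ed <- data.frame(a = c("g1", "g2"), b = c("g2", "g3"),
                   weight = c(0.5, 0.9))
  write_edge_list(ed, f)
  back <- read_edge_list(f)
  expect_equal(back, ed)
})
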
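test_that("discretization centres, clips and matches an independent histogram", {
  with_seed_helper(1, s <- rnorm(500, mean = 2, sd = 3))
  d <- fit_discretizer(score_table("T", data.frame(a = sprintf("a%d", 1:500),
                                                   b = sprintf("b%d", 1:500)), s),
                       n_bins = 10)
  m <- mean(s); sdev <- sd(s)
  expect_equal(d$edges[1], m - 5 * sdev)
  expect_equal(d$edges[11], m + 5 * sdev)
  # the mean falls into the lower-middle bin under the half-open convention
  expect_identical(discretize(d, m), 6L)          # 1-based bin 6 = 0-based 5
  expect_identical(discretize(d, m + 100 * sdev), 10L)
  expect_identical(discretize(d, m - 100 * sdev), 1L)

  with_seed_helper(2, u <- runif(2000, -1, 1))
  d2 <- fit_discretizer(u, n_bins = 10)
  got <- tabulate(discretize(d2, u), 10)
  oracle <- tabulate(cut(u, breaks = d2$edges, right = FALSE,
                         labels = FALSE), 10)
  expect_equal(got, oracle)

  expect_warning(d3 <- fit_discretizer(rep(1.5, 10)), "zero score variance")
  expect_identical(d3$n_bins, 1L)
  expect_identical(discretize(d3, c(-100, 1.5, 100)), rep(1L, 3))
})

test_that("observation CPTs implement smoothed maximum likelihood counting", {
  pairs <- data.frame(a = sprintf("a%d", 1:6), b = sprintf("b%d", 1:6))
  # bins: 2-bin scheme over [-1, 1); scores -0.5 -> bin 1, 0.5 -> bin 2
  d <- structure(list(term = "T", mean = 0, sd = 1, n_bins = 2L,
                      edges = c(-1, 0, 1)), class = "discretization_scheme")
  sc <- score_table("T", pairs, c(0.5, 0.5, 0.5, -0.5, -0.5, -0.5))
  ls <- pair_label_set("T", pairs[1:4, ], pairs[5:6, ])
  # X=1 bin counts: (1, 3); alpha = 1 -> (2/6, 4/6)
  cpt <- learn_observation_cpt(sc, ls, d, pseudocount = 1)
  expect_equal(unname(cpt$p[, "1"]), c(2 / 6, 4 / 6))
  expect_equal(unname(cpt$p[, "0"]), c(3 / 4, 1 / 4))
  expect_equal(colSums(cpt$p), c("0" = 1, "1" = 1))

  # alpha = 0: raw ML, all X=0 mass in bin 1
  cpt0 <- learn_observation_cpt(sc, ls, d, pseudocount = 0)
  expect_equal(unname(cpt0$p[, "0"]), c(1, 0))

  # random counting oracle
  for (seed in 1:5) {
    with_seed_helper(seed, {
      n <- 40
      p2 <- data.frame(a = sprintf("a%d", 1:n), b = sprintf("b%d", 1:n))
      s2 <- rnorm(n)
      is_pos <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.6, .4))
    })
    if (!any(is_pos) || all(is_pos)) next
    sc2 <- score_table("T", p2, s2)
    d2 <- fit_discretizer(sc2, n_bins = 5)
    ls2 <- pair_label_set("T", p2[is_pos, ], p2[!is_pos, ])
    cpt2 <- learn_observation_cpt(sc2, ls2, d2, pseudocount = 1)
    for (x in c(TRUE, FALSE)) {
      cnt <- tabulate(discretize(d2, s2[is_pos == x]), 5)
      expect_equal(unname(cpt2$p[, if (x) "1" else "0"]),
                   (cnt + 1) / (sum(cnt) + 5))
    }
  }
})

test_that("structural CPTs count parent positives among child-negative pairs", {
  o <- interaction_ontology(data.frame(
    id = c("R", "A", "B"), parent = c(NA, "R", "R"), directed = FALSE,
    name = ""))
  g <- function(i) sprintf("g%02d", i)
  # A positives: pairs 1-2; B positives: pair 3; R positives: 1-4 (propagated + own)
  pA <- data.frame(a = g(c(1, 3)), b = g(c(2, 4)))
  pB <- data.frame(a = g(5), b = g(6))
  pR <- rbind(pA, pB, data.frame(a = g(7), b = g(8)))
  nR <- data.frame(a = g(c(9, 11)), b = g(c(10, 12)))
  labs <- list(
    R = pair_label_set("R", pR, nR),
    A = pair_label_set("A", pA, data.frame(a = g(13), b = g(14))),
    B = pair_label_set("B", pB, data.frame(a = g(15), b = g(16))))
  cpts <- learn_structural_cpts(o, labs, pseudocount = 1)
  # R: labeled pairs 4 pos + 2 neg; child-positive: 3 -> conditioning set
  # size 3 (1 pos + 2 neg); q = (1 + 1) / (3 + 2)
  expect_equal(cpts$R$q, 2 / 5)
  # leaves: q is the smoothed marginal prior
  expect_equal(cpts$A$q, (2 + 1) / (3 + 2))
  expect_equal(cpts$B$q, (1 + 1) / (2 + 2))

  # every parent-positive pair has a positive child -> q ~ alpha / (n + 2 alpha)
  labs2 <- list(
    R = pair_label_set("R", rbind(pA, pB), nR),
    A = labs$A, B = labs$B)
  cpts2 <- learn_structural_cpts(o, labs2, pseudocount = 1)
  expect_equal(cpts2$R$q, 1 / 4)  # 0 positives among 2 child-negative pairs

  # inconsistent labels (child positive, parent negative) are rejected
  labs3 <- labs
  labs3$A <- pair_label_set("A", rbind(pA, nR[1, ]),
                            data.frame(a = g(13), b = g(14)))
  expect_error(learn_structural_cpts(o, labs3), "hierarchy violation")
})

test_that("single-term posterior follows Bayes rule", {
  o <- interaction_ontology(data.frame(id = "T", parent = NA,
                                       directed = FALSE, name = ""))
  # prior 0.5, likelihood ratio 3 at the observed bin -> posterior 0.75
  m <- toy_model(o, q = list(T = 0.5), L0 = list(T = 0.25),
                 L1 = list(T = 0.75))
  post <- infer_posteriors(m, matrix(-0.5, 1, 1, dimnames = list(NULL, "T")),
                           pairs = data.frame(a = "g1", b = "g2"))
  expect_equal(unname(post$posterior[1, "T"]), 0.75)
})

test_that("exact inference matches exhaustive enumeration on random decorated trees", {
  with_seed_helper(2024, {
    for (rep in 1:40) {
      nt <- sample(2:10, 1)
      o <- interaction_ontology(random_tree_terms(nt))
      ids <- o$terms$id
      q <- as.list(stats::setNames(runif(nt, 0.02, 0.98), ids))
      L0 <- as.list(stats::setNames(runif(nt, 0.01, 1), ids))
      L1 <- as.list(stats::setNames(runif(nt, 0.01, 1), ids))
      m <- toy_model(o, q, L0, L1)
      obs_bin <- sample(c(-0.5, 0.5, NA), nt, replace = TRUE,
                        prob = c(.45, .45, .1))
      S <- matrix(obs_bin, 1, nt, dimnames = list(NULL, ids))
      post <- infer_posteriors(m, S, pairs = data.frame(a = "x", b = "y"))
      # enumeration oracle with per-term likelihood of the observed bin
      eL0 <- lapply(ids, function(t) {
        if (is.na(S[, t])) 1 else if (S[, t] < 0) L0[[t]] else 1 - L0[[t]]
      })
      eL1 <- lapply(ids, function(t) {
        if (is.na(S[, t])) 1 else if (S[, t] < 0) L1[[t]] else 1 - L1[[t]]
      })
      names(eL0) <- names(eL1) <- ids
      oracle <- enum_posteriors(o, q, eL0, eL1)
      expect_lt(max(abs(post$posterior[1, ids] - oracle[ids])), 1e-9)
    }
  })
})

test_that("uninformative evidence returns the structural prior, informative evidence moves monotonically", {
  with_seed_helper(7, {
    o <- interaction_ontology(random_tree_terms(6))
    ids <- o$terms$id
    q <- as.list(stats::setNames(runif(6, 0.1, 0.9), ids))
    flat <- as.list(stats::setNames(rep(0.5, 6), ids))
    m_flat <- toy_model(o, q, flat, flat)
    S <- matrix(-0.5, 1, 6, dimnames = list(NULL, ids))
    post <- infer_posteriors(m_flat, S, pairs = data.frame(a = "x", b = "y"))
    prior <- enum_posteriors(o, q, as.list(stats::setNames(rep(1, 6), ids)),
                             as.list(stats::setNames(rep(1, 6), ids)))
    expect_equal(unname(post$posterior[1, ids]), unname(prior[ids]),
                 tolerance = 1e-12)

    # raising one term's likelihood ratio never lowers its posterior
    t0 <- ids[3]
    prev <- -Inf
    for (lr in c(0.5, 1, 2, 5, 20)) {
      L0 <- flat; L1 <- flat
      L0[[t0]] <- 0.5 / sqrt(lr); L1[[t0]] <- min(0.99, 0.5 * sqrt(lr))
      mm <- toy_model(o, q, L0, L1)
      p <- infer_posteriors(mm, S, pairs = data.frame(a = "x", b = "y"))
      expect_gte(p$posterior[1, t0], prev - 1e-12)
      prev <- p$posterior[1, t0]
    }
  })
})

test_that("posteriors respect parent >= child on chains and random models", {
  with_seed_helper(11, {
    for (rep in 1:10) {
      nt <- sample(3:9, 1)
      o <- interaction_ontology(random_tree_terms(nt))
      ids <- o$terms$id
      m <- toy_model(o,
                     as.list(stats::setNames(runif(nt, .05, .95), ids)),
                     as.list(stats::setNames(runif(nt, .05, .95), ids)),
                     as.list(stats::setNames(runif(nt, .05, .95), ids)))
      S <- matrix(sample(c(-0.5, 0.5), 5 * nt, replace = TRUE), 5, nt,
                  dimnames = list(NULL, ids))
      post <- infer_posteriors(m, S, pairs = data.frame(a = sprintf("x%d", 1:5),
                                                        b = sprintf("y%d", 1:5)))
      for (t in ids) {
        for (ch in o$children[[t]]) {
          expect_true(all(post$posterior[, t] >= post$posterior[, ch] - 1e-9))
        }
      }
    }
  })
})

test_that("the MAP assignment is hierarchy-consistent and matches enumeration", {
  with_seed_helper(13, {
    for (rep in 1:15) {
      nt <- sample(2:8, 1)
      o <- interaction_ontology(random_tree_terms(nt))
      ids <- o$terms$id
      q <- as.list(stats::setNames(runif(nt, .05, .95), ids))
      L0 <- as.list(stats::setNames(runif(nt, .05, .95), ids))
      L1 <- as.list(stats::setNames(runif(nt, .05, .95), ids))
      m <- toy_model(o, q, L0, L1)
      S <- matrix(sample(c(-0.5, 0.5), nt, replace = TRUE), 1, nt,
                  dimnames = list(NULL, ids))
      got <- map_assignment(m, S, pairs = data.frame(a = "x", b = "y"))[1, ]
      # enumeration oracle for the joint mode
      configs <- as.matrix(expand.grid(rep(list(0:1), nt)))
      colnames(configs) <- ids
      jp <- apply(configs, 1, function(x) {
        p <- 1
        for (t in ids) {
          ch <- o$children[[t]]
          pr1 <- if (length(ch) && any(x[ch] == 1)) 1 else q[[t]]
          l <- if (S[, t] < 0) {
            if (x[t] == 1) L1[[t]] else L0[[t]]
          } else {
            if (x[t] == 1) 1 - L1[[t]] else 1 - L0[[t]]
          }
          p <- p * (if (x[t] == 1) pr1 else 1 - pr1) * l
        }
        p
      })
      best <- configs[which.max(jp), ]
      expect_equal(unname(got[ids] * 1), unname(best[ids]))
      for (t in ids) {
        for (ch in o$children[[t]]) {
          expect_true(!got[ch] || got[t])
        }
      }
    }
  })
})

test_that("the composed pipeline equals running score, discretize, infer by hand", {
  ex <- cached_small_experiment(1)
  o <- ex$ontology
  terms <- o$terms$id
  pairs <- ex$pairs[1:50, ]
  fts <- lapply(stats::setNames(terms, terms), function(t) {
    apply_standardizer(synth_features(ex$feature_model, pairs, t),
                       ex$standardizers[[t]])
  })
  post_pipe <- predict_pipeline(ex$model, ex$classifiers, fts)
  # manual composition
  S <- sapply(terms, function(t) predict_scores(ex$classifiers[[t]],
                                                fts[[t]])$scores)
  post_manual <- infer_posteriors(ex$model, S, pairs = pairs)
  expect_equal(post_pipe$posterior, post_manual$posterior)

  # orientation swap on undirected terms leaves posteriors unchanged
  und <- terms[!o$terms$directed]
  flipped <- data.frame(a = pairs$b, b = pairs$a)
  fts_f <- lapply(stats::setNames(und, und), function(t) {
    apply_standardizer(synth_features(ex$feature_model, flipped, t),
                       ex$standardizers[[t]])
  })
  for (t in und) {
    expect_equal(predict_scores(ex$classifiers[[t]], fts_f[[t]])$scores,
                 predict_scores(ex$classifiers[[t]], fts[[t]])$scores)
  }
})
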
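test_that("adaptive threshold follows the bracket rule and its tie-break", {
  expect_equal(adaptive_evalue_threshold(107)$t, 1e-3)
  expect_equal(adaptive_evalue_threshold(155)$t, 1e-3)
  expect_equal(adaptive_evalue_threshold(11)$t, 1e-2)
  # X = 10 satisfies both brackets (10^0 <= 10 <= 10^1 and
  # 10^1 <= 10 <= 10^2); the smaller n wins
  th <- adaptive_evalue_threshold(10)
  expect_equal(th$n, 1L)
  expect_equal(th$t, 1e-1)
  expect_true(10^(th$n - 1) <= 10 && 10 <= 10^th$n)
  expect_error(adaptive_evalue_threshold(0), "positive")
})

test_that("adaptive threshold is non-increasing in the motif count", {
  ts <- vapply(c(1, 5, 10, 50, 99, 100, 101, 1000, 5000),
               function(x) adaptive_evalue_threshold(x)$t, numeric(1))
  expect_true(all(diff(ts) <= 0))
})

test_that("motif similarity emits edges for homologs only", {
  m <- random_aa(38, seed = 11)
  motifs <- tibble::tibble(id = c("a", "b"), sequence = c(m, m))
  e <- pairwise_motif_similarity(motifs, t = 1e-3)
  expect_equal(nrow(e), 1L)
  expect_gt(e$weight, 10)

  # unrelated random motifs: expected E-value far above threshold
  motifs2 <- tibble::tibble(id = c("a", "b"),
                            sequence = c(random_aa(38, 1), random_aa(38, 2)))
  expect_equal(nrow(pairwise_motif_similarity(motifs2, t = 1e-3)), 0L)

  # a single motif has no pairs
  expect_equal(nrow(pairwise_motif_similarity(motifs[1, ], t = 1)), 0L)
})

test_that("identity edges require 90% mutual coverage and weight by identity", {
  m <- random_aa(38, seed = 21)
  motifs <- tibble::tibble(id = c("a", "b"), sequence = c(m, m))
  e <- identity_edges(motifs)
  expect_equal(e$weight, 100)

  # one substitution in 38 residues: identity about 37/38
  m2 <- m
  substr(m2, 19, 19) <- if (substr(m, 19, 19) == "A") "V" else "A"
  e2 <- identity_edges(tibble::tibble(id = c("a", "b"),
                                      sequence = c(m, m2)))
  expect_equal(e2$weight, 100 * 37 / 38, tolerance = 1e-6)

  # motifs sharing only half their length fail the coverage rule
  half <- paste0(substr(m, 1, 19), random_aa(19, 5))
  e3 <- identity_edges(tibble::tibble(id = c("a", "b"),
                                      sequence = c(m, half)))
  expect_equal(nrow(e3), 0L)
})

test_that("MCL separates disconnected components and keeps singletons", {
  tri <- function(nodes) tibble::tibble(
    node_a = nodes[c(1, 2, 3)], node_b = nodes[c(2, 3, 1)], weight = 10)
  e <- rbind(tri(c("a", "b", "c")), tri(c("d", "e", "f")))
  cl <- markov_cluster(e, inflation = 2)
  expect_equal(cl$n_clusters, 2L)
  part <- tidy(cl)
  expect_equal(length(unique(part$cluster[part$node %in% c("a", "b", "c")])), 1L)

  single <- markov_cluster(e[0, ], inflation = 2, nodes = "x")
  expect_equal(single$n_clusters, 1L)
  expect_equal(tidy(single)$node, "x")
})

test_that("MCL splits a weakly bridged barbell at high inflation", {
  clique <- function(nodes) {
    p <- t(utils::combn(nodes, 2))
    tibble::tibble(node_a = p[, 1], node_b = p[, 2], weight = 10)
  }
  e <- rbind(clique(paste0("l", 1:4)), clique(paste0("r", 1:4)),
             tibble::tibble(node_a = "l1", node_b = "r1", weight = 0.5))
  cl <- markov_cluster(e, inflation = 5)
  expect_equal(cl$n_clusters, 2L)
  ref <- reference_mcl(e, unique(c(e$node_a, e$node_b)), inflation = 5)
  got <- stats::setNames(cl$partition$cluster, cl$partition$node)
  expect_true(same_partition(got, ref))
})

test_that("MCL agrees with an independent reference on random fixture graphs", {
  for (seed in 1:20) {
    g <- withr::with_seed(seed, {
      n <- sample(6:14, 1)
      nodes <- paste0("n", seq_len(n))
      # planted two-block structure with sparse cross edges
      block <- rep(1:2, length.out = n)
      p <- t(utils::combn(nodes, 2))
      same <- block[match(p[, 1], nodes)] == block[match(p[, 2], nodes)]
      keep <- stats::runif(nrow(p)) < ifelse(same, 0.9, 0.1)
      list(edges = tibble::tibble(node_a = p[keep, 1], node_b = p[keep, 2],
                                  weight = stats::runif(sum(keep), 1, 10)),
           nodes = nodes)
    })
    cl <- suppressWarnings(
      markov_cluster(g$edges, inflation = 2, nodes = g$nodes))
    ref <- reference_mcl(g$edges, g$nodes, inflation = 2)
    got <- stats::setNames(cl$partition$cluster, cl$partition$node)
    expect_true(same_partition(got, ref),
                label = paste("agreement with reference MCL, seed", seed))
  }
})

test_that("MCL is invariant under node relabeling and never merges components", {
  e <- tibble::tibble(node_a = c("a", "b", "c", "x"),
                      node_b = c("b", "c", "a", "y"),
                      weight = c(5, 5, 5, 2))
  cl1 <- markov_cluster(e, inflation = 2)
  # relabel and permute rows
  map <- c(a = "q", b = "r", c = "s", x = "t", y = "u")
  e2 <- tibble::tibble(node_a = unname(map[e$node_a]),
                       node_b = unname(map[e$node_b]),
                       weight = e$weight)[c(3, 1, 4, 2), ]
  cl2 <- markov_cluster(e2, inflation = 2)
  p1 <- stats::setNames(cl1$partition$cluster, map[cl1$partition$node])
  p2 <- stats::setNames(cl2$partition$cluster, cl2$partition$node)
  expect_true(same_partition(p1, p2))
  # x/y never co-clusters with the triangle (different components)
  part <- cl1$partition
  expect_false(part$cluster[part$node == "x"] %in%
                 part$cluster[part$node %in% c("a", "b", "c")])
})

test_that("cluster count is non-decreasing in inflation on a fixed graph", {
  e <- withr::with_seed(42, {
    nodes <- paste0("n", 1:12)
    p <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(p)) < 0.4
    tibble::tibble(node_a = p[keep, 1], node_b = p[keep, 2],
                   weight = stats::runif(sum(keep), 0.5, 10))
  })
  ks <- vapply(c(1.5, 2, 3, 5), function(I) {
    suppressWarnings(markov_cluster(e, inflation = I)$n_clusters)
  }, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("tenths-scaled inflation values are accepted", {
  e <- tibble::tibble(node_a = "a", node_b = "b", weight = 5)
  expect_equal(markov_cluster(e, inflation = 50)$inflation, 5)
})
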
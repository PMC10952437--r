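test_that("edge density is realized over potential connections", {
  expect_equal(edge_density(net_from_weights(matrix(1, 5, 5) - diag(5))), 1)
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 0.3
  path3[2, 3] <- path3[3, 2] <- 0.6
  expect_equal(edge_density(net_from_weights(path3)), 2 / 3)
  expect_equal(edge_density(net_from_weights(matrix(0, 4, 4))), 0)
  expect_error(edge_density(net_from_weights(matrix(0, 1, 1))), "2 nodes")
})

test_that("global clustering is the triangle-to-triple ratio", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(global_clustering(net_from_weights(tri)), 1)
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_clustering(net_from_weights(path3)), 0)
  # triangle ABC plus pendant edge CD: 3 triangles-counts / 5 triples = 0.6
  paw <- matrix(0, 4, 4)
  paw[1, 2] <- paw[2, 1] <- 1; paw[2, 3] <- paw[3, 2] <- 1
  paw[1, 3] <- paw[3, 1] <- 1; paw[3, 4] <- paw[4, 3] <- 1
  expect_equal(global_clustering(net_from_weights(paw)), 0.6)
  # no connected triple: undefined
  pair <- matrix(0, 4, 4); pair[1, 2] <- pair[2, 1] <- 1
  expect_true(is.na(global_clustering(net_from_weights(pair))))
})

test_that("mean edge weight averages positive weights only", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 0.5
  expect_equal(mean_edge_weight(net_from_weights(w)), 0.75)
  expect_error(mean_edge_weight(net_from_weights(matrix(0, 3, 3))),
               "no positive edges")
})

test_that("binary metrics match enumeration oracles on random graphs", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    w <- matrix(0, n, n)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (runif(1) < 0.5) w[a, b] <- w[b, a] <- runif(1, 0.05, 1)
    }
    net <- net_from_weights(w)
    expect_equal(edge_density(net), density_oracle(w))
    expect_equal(global_clustering(net), clustering_oracle(w))
    if (any(w > 0)) expect_equal(mean_edge_weight(net), mew_oracle(w))
  }
})

test_that("two disjoint unit triangles have modularity 1/2 at the natural split", {
  w <- matrix(0, 6, 6)
  for (blk in list(1:3, 4:6)) {
    for (a in blk) for (b in blk) if (a != b) w[a, b] <- 1
  }
  net <- net_from_weights(w)
  m <- rep(1:2, each = 3)
  expect_equal(modularity_q(net, m), 0.5)
  cl <- edge_betweenness_communities(net)
  expect_equal(cl$modularity, 0.5)
  expect_equal(length(unique(cl$membership)), 2)

  # any single-community partition has Q = 0 by construction
  full <- net_from_weights(matrix(1, 4, 4) - diag(4))
  expect_equal(modularity_q(full, rep(1, 4)), 0)
})

test_that("equal-weight blocks match the closed-form modularity 1 - 1/k", {
  for (k in 2:4) {
    n <- 3 * k
    w <- matrix(0, n, n)
    for (b in seq_len(k)) {
      ix <- ((b - 1) * 3 + 1):(b * 3)
      for (a in ix) for (c in ix) if (a != c) w[a, c] <- 0.7
    }
    m <- rep(seq_len(k), each = 3)
    expect_equal(modularity_q(net_from_weights(w), m),
                 sum(rep(1 / k - 1 / k^2, k)))
  }
})

test_that("edge-betweenness cut reaches the exhaustive optimum on planted blocks", {
  parts <- all_set_partitions(8)
  for (seed in 1:5) {
    g <- two_block_graph(seed)
    net <- net_from_weights(g$weights)
    found <- edge_betweenness_communities(net)
    best <- best_partition_q_oracle(g$weights, parts)
    expect_equal(found$modularity, best, tolerance = 1e-9)
  }
})

test_that("metrics are invariant under node relabelling", {
  set.seed(5)
  w <- matrix(0, 6, 6)
  for (a in 1:5) for (b in (a + 1):6) {
    if (runif(1) < 0.6) w[a, b] <- w[b, a] <- runif(1)
  }
  dimnames(w) <- list(letters[1:6], letters[1:6])
  perm <- sample(6)
  w2 <- w[perm, perm]
  n1 <- net_from_weights(w)
  n2 <- net_from_weights(w2)
  expect_equal(edge_density(n1), edge_density(n2))
  expect_equal(global_clustering(n1), global_clustering(n2))
  expect_equal(mean_edge_weight(n1), mean_edge_weight(n2))
  expect_equal(edge_betweenness_communities(n1)$modularity,
               edge_betweenness_communities(n2)$modularity, tolerance = 1e-12)
})

test_that("the metric summary carries flags and handles degenerate networks", {
  full <- net_from_weights(matrix(0.4, 4, 4) - diag(0.4, 4))
  row <- summarize_network(full)
  expect_true(row$fully_connected)
  expect_equal(row$edge_density, 1)
  expect_true(row$zero_modularity_flag)

  w1 <- matrix(0, 3, 3); w1[1, 2] <- w1[2, 1] <- 0.4
  row1 <- summarize_network(net_from_weights(w1))
  expect_false(row1$usable_for_metrics)
  expect_true(is.na(row1$modularity_q))
  expect_match(row1$notes, "fewer than 2 edges")

  g <- two_block_graph(3)
  row2 <- summarize_network(net_from_weights(g$weights))
  expect_false(row2$zero_modularity_flag)
})
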
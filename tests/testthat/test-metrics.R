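test_that("unit-weight toy graphs reproduce hand values", {
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1
  tri <- tri + t(tri)
  nm <- nodal_metrics(weighted_network(tri))
  expect_equal(nm$strength, rep(2, 3))
  expect_equal(nm$clustering, rep(1, 3))
  expect_equal(nm$shortest_path_length, rep(1, 3))
  expect_equal(nm$global_efficiency, rep(1, 3))

  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 3] <- 1
  path <- path + t(path)
  nmp <- nodal_metrics(weighted_network(path))
  expect_equal(nmp$strength, c(1, 2, 1))
  d <- funcnet:::shortest_distances(path)
  expect_equal(d[1, 3], 2)

  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  gm <- global_metrics(weighted_network(k5), n_null = 2, seed = 1)
  expect_equal(gm$clustering_coefficient, 1)
  expect_equal(gm$shortest_path_length, 1)
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$network_strength, 4)
})

test_that("all nodal metrics match the brute-force oracle on random graphs", {
  for (seed in 1:6) {
    net <- rand_weighted_net(10, p = 0.45, seed = seed)
    nm <- nodal_metrics(net)
    or <- oracle_nodal(net$weights)
    expect_equal(nm$strength, or$strength, tolerance = 1e-9)
    expect_equal(nm$clustering, or$clustering, tolerance = 1e-9)
    expect_equal(nm$shortest_path_length, or$shortest_path_length,
                 tolerance = 1e-9)
    expect_equal(nm$global_efficiency, or$global_efficiency, tolerance = 1e-9)
    expect_equal(nm$local_efficiency, or$local_efficiency, tolerance = 1e-9)
  }
})

test_that("isolated nodes get zero strength/clustering/efficiency", {
  w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 0.5
  nm <- nodal_metrics(weighted_network(w))
  expect_equal(nm$strength[3], 0)
  expect_equal(nm$global_efficiency[3], 0)
  expect_equal(nm$local_efficiency[3], 0)
  expect_equal(nm$clustering[3], 0)
  expect_true(is.na(nm$shortest_path_length[3]))
})

test_that("identity nulls give gamma = lambda = sigma = 1", {
  net <- rand_weighted_net(12, p = 0.5, seed = 3)
  gm <- global_metrics(net, null_networks = rep(list(net), 5))
  expect_equal(gm$gamma, 1, tolerance = 1e-12)
  expect_equal(gm$lambda, 1, tolerance = 1e-12)
  expect_equal(gm$small_worldness, 1, tolerance = 1e-12)
  # sigma = gamma / lambda exactly, always
  gm2 <- global_metrics(net, n_null = 10, seed = 5)
  expect_equal(gm2$small_worldness, gm2$gamma / gm2$lambda, tolerance = 1e-12)
})

test_that("rewired nulls preserve degrees and the weight multiset", {
  for (seed in 1:4) {
    net <- rand_weighted_net(15, p = 0.3, seed = seed)
    rn <- rewire_null(net, seed = seed + 10)
    expect_equal(rowSums(rn$adjacency), rowSums(net$adjacency))
    expect_equal(sort(rn$weights[upper.tri(rn$weights)]),
                 sort(net$weights[upper.tri(net$weights)]))
    expect_gt(rn$provenance$swaps, 0)
    # deterministic in (net, seed)
    rn2 <- rewire_null(net, seed = seed + 10)
    expect_identical(rn$weights, rn2$weights)
  }
})

test_that("a triangle cannot be rewired", {
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- c(0.2, 0.5, 0.9)
  tri <- tri + t(tri)
  net <- weighted_network(tri)
  rn <- rewire_null(net, seed = 2)
  expect_identical(rn$weights, net$weights)
  expect_equal(rn$provenance$swaps, 0)
})

test_that("a ring lattice with light rewiring is small-world", {
  set.seed(9)
  n <- 90; khalf <- 5
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(khalf)) {
      j <- ((i + s - 1) %% n) + 1
      w[i, j] <- w[j, i] <- 1
    }
  }
  # rewire 10% of edges
  net <- weighted_network(w)
  p <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  move <- sample(nrow(p), round(0.1 * nrow(p)))
  for (e in move) {
    i <- p[e, 1]
    cand <- which(w[i, ] == 0 & seq_len(n) != i)
    j2 <- sample(cand, 1)
    w[p[e, 1], p[e, 2]] <- w[p[e, 2], p[e, 1]] <- 0
    w[i, j2] <- w[j2, i] <- 1
  }
  gm <- global_metrics(weighted_network(w), n_null = 100, seed = 17)
  expect_gt(gm$small_worldness, 1)
})

test_that("dense random graphs have sigma near 1", {
  net <- rand_weighted_net(90, p = 0.5, seed = 23, wmin = 0.4, wmax = 1)
  gm <- global_metrics(net, n_null = 50, seed = 29)
  expect_gt(gm$small_worldness, 0.8)
  expect_lt(gm$small_worldness, 1.2)
})

test_that("global efficiency is non-decreasing when a weight increases", {
  net <- rand_weighted_net(10, p = 0.35, seed = 31)
  gm0 <- global_metrics(net, n_null = 1, seed = 1)$global_efficiency
  w <- net$weights
  on <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  for (e in seq_len(min(4, nrow(on)))) {
    w2 <- w
    w2[on[e, 1], on[e, 2]] <- w2[on[e, 2], on[e, 1]] <- w[on[e, 1], on[e, 2]] + 0.5
    gm1 <- global_metrics(weighted_network(w2), n_null = 1,
                          seed = 1)$global_efficiency
    expect_gte(gm1, gm0 - 1e-12)
  }
})

test_that("metrics are equivariant under node relabelling", {
  net <- rand_weighted_net(11, p = 0.4, seed = 37)
  set.seed(38)
  perm <- sample(11)
  wp <- net$weights[perm, perm]
  netp <- weighted_network(wp)
  nm <- nodal_metrics(net); nmp <- nodal_metrics(netp)
  for (m in c("strength", "clustering", "global_efficiency",
              "local_efficiency")) {
    expect_equal(nmp[[m]], nm[[m]][perm], tolerance = 1e-12)
  }
  gm <- global_metrics(net, null_networks = rep(list(net), 2))
  gmp <- global_metrics(netp, null_networks = rep(list(netp), 2))
  for (m in c("network_strength", "clustering_coefficient",
              "shortest_path_length", "global_efficiency",
              "local_efficiency", "hierarchy", "assortativity")) {
    expect_equal(gmp[[m]], gm[[m]], tolerance = 1e-10)
  }
})

test_that("assortativity matches the independent graph-library value", {
  net <- rand_weighted_net(20, p = 0.3, seed = 41)
  gm <- global_metrics(net, n_null = 1, seed = 1)
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  expect_equal(gm$assortativity, igraph::assortativity_degree(g),
               tolerance = 1e-10)
})
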
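test_that("complete graphs have phi = 1 at every defined level", {
  k6 <- matrix(1, 6, 6); diag(k6) <- 0
  rc <- rich_club_curve(weighted_network(k6), n_null = 2, seed = 1)
  def <- is.finite(rc$phi)
  expect_true(any(def))
  expect_true(all(rc$phi[def] == 1))
})

test_that("identity nulls normalize the curve to 1", {
  net <- rand_weighted_net(14, p = 0.4, seed = 2)
  rc <- rich_club_curve(net, null_networks = rep(list(net), 3))
  def <- is.finite(rc$phi_norm)
  expect_true(all(abs(rc$phi_norm[def] - 1) < 1e-12))
})

test_that("phi matches direct enumeration on random graphs", {
  for (seed in 1:5) {
    net <- rand_weighted_net(12, p = 0.45, seed = seed)
    rc <- rich_club_curve(net, n_null = 1, seed = 1)
    for (row in seq_len(nrow(rc))) {
      expect_equal(rc$phi[row], oracle_phi(net$weights, rc$k[row]),
                   tolerance = 1e-9)
    }
  }
})

test_that("a planted club yields phi_norm > 1 at the top defined level", {
  set.seed(5)
  n <- 45
  w <- matrix(0, n, n)
  # sparse periphery
  up <- which(upper.tri(w))
  on <- sample(up, 80)
  w[on] <- runif(80, 0.05, 0.2)
  w <- w + t(w)
  # 5 fully interconnected high-strength nodes
  club <- 1:5
  for (i in club) for (j in club) if (i < j) w[i, j] <- w[j, i] <- 0.9
  # attach the club to the periphery so its degree dominates
  for (i in club) {
    for (j in sample(6:n, 10)) w[i, j] <- w[j, i] <- pmax(w[i, j], 0.1)
  }
  diag(w) <- 0
  net <- weighted_network(w)
  rc <- rich_club_curve(net, n_null = 100, seed = 7)
  top <- max(rc$k[is.finite(rc$phi_norm)])
  expect_gt(rc$phi_norm[rc$k == top], 1)
})

test_that("hub counts follow the ceiling rule at 10/15/20 percent", {
  # continuous strength ranking: boundary ties have probability zero
  nets <- lapply(1:4, function(s) rand_weighted_net(90, p = 0.2, seed = s))
  expect_length(identify_hubs(nets, 0.15, ranking = "strength"), 14)
  expect_length(identify_hubs(nets, 0.10, ranking = "strength"), 9)
  expect_length(identify_hubs(nets, 0.20, ranking = "strength"), 18)
})

test_that("hub selection recovers a known ranking", {
  # star + one peripheral edge: center degree 9, nodes 2-3 degree 2, rest 1
  n <- 10
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  net <- weighted_network(w)
  hubs <- identify_hubs(list(net), fraction = 0.1)
  expect_equal(as.character(hubs), net$region_labels[1])
  # strength ranking oracle on continuous distinct weights
  net2 <- rand_weighted_net(12, p = 0.6, seed = 71)
  s <- rowSums(net2$weights)
  hubs_s <- identify_hubs(list(net2), fraction = 0.25, ranking = "strength")
  expect_setequal(as.character(hubs_s),
                  net2$region_labels[order(s, decreasing = TRUE)[1:3]])
})

test_that("boundary ties inflate the hub set and are recorded", {
  w <- matrix(0, 6, 6)
  w[1, 2:5] <- 1; w[2:5, 1] <- 1  # node 1 degree 4, nodes 2..5 degree 1
  net <- weighted_network(w)
  hubs <- identify_hubs(list(net), fraction = 0.34)  # ceiling = 3
  expect_gte(length(hubs), 3)
  expect_equal(length(hubs), 3 + attr(hubs, "tie_inflation"))
})

test_that("edge classes partition the edges and conserve total strength", {
  for (seed in 1:4) {
    net <- rand_weighted_net(12, p = 0.5, seed = seed)
    set.seed(seed)
    hubs <- sample(net$region_labels, 3)
    ec <- classify_connections(net, hubs)
    # brute-force per-edge check
    for (row in seq_len(nrow(ec$edges))) {
      i_h <- ec$edges$region_i[row] %in% hubs
      j_h <- ec$edges$region_j[row] %in% hubs
      want <- if (i_h && j_h) "rich_club" else if (i_h || j_h) "feeder"
              else "local"
      expect_equal(ec$edges$class[row], want)
    }
    expect_equal(sum(ec$summary$degree), sum(net$adjacency) / 2)
    expect_equal(sum(ec$summary$strength),
                 sum(net$weights[upper.tri(net$weights)]), tolerance = 1e-12)
  }
})

test_that("degenerate hub sets give pure feeder / rich-club classes", {
  star <- matrix(0, 5, 5); star[1, 2:5] <- 0.5; star[2:5, 1] <- 0.5
  net <- weighted_network(star)
  ec <- classify_connections(net, net$region_labels[1])
  expect_equal(ec$summary$degree[ec$summary$class == "feeder"], 4)
  expect_equal(ec$summary$degree[ec$summary$class == "local"], 0)
  ec_all <- classify_connections(net, net$region_labels)
  expect_equal(ec_all$summary$degree[ec_all$summary$class == "rich_club"], 4)
  expect_true(is.na(ec_all$summary$average_strength[
    ec_all$summary$class == "local"]))
})

test_that("random graphs have normalized rich club near 1 on average", {
  vals <- vapply(1:50, function(s) {
    net <- rand_weighted_net(50, p = 0.3, seed = 100 + s,
                             wmin = 0.2, wmax = 1)
    rc <- rich_club_curve(net, n_null = 100, seed = 200 + s)
    mean(rc$phi_norm[is.finite(rc$phi_norm)])
  }, numeric(1))
  expect_gt(mean(vals), 0.9)
  expect_lt(mean(vals), 1.1)
})
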
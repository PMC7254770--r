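make_global_list <- function(values_by_metric, n) {
  lapply(seq_len(n), function(i) {
    g <- list(network_strength = values_by_metric$network_strength[i],
              clustering_coefficient = values_by_metric$clustering_coefficient[i],
              shortest_path_length = values_by_metric$shortest_path_length[i],
              small_worldness = values_by_metric$small_worldness[i],
              global_efficiency = values_by_metric$global_efficiency[i],
              local_efficiency = values_by_metric$local_efficiency[i],
              hierarchy = values_by_metric$hierarchy[i],
              assortativity = values_by_metric$assortativity[i])
    class(g) <- "fn_global_metrics"
    g
  })
}

rand_globals <- function(n, seed, shift = 0) {
  set.seed(seed)
  vals <- list()
  for (m in c("network_strength", "clustering_coefficient",
              "shortest_path_length", "small_worldness",
              "global_efficiency", "local_efficiency", "hierarchy",
              "assortativity")) {
    vals[[m]] <- rnorm(n) + shift
  }
  make_global_list(vals, n)
}

test_that("identical groups give t = 0, p = 1; labels swap antisymmetrically", {
  ga <- rand_globals(5, 1)
  tab <- compare_global(ga, ga)
  expect_true(all(tab$statistic == 0))
  expect_true(all(tab$p == 1))
  gb <- rand_globals(5, 2, shift = 0.5)
  t_ab <- compare_global(ga, gb)
  t_ba <- compare_global(gb, ga)
  expect_equal(t_ab$statistic, -t_ba$statistic, tolerance = 1e-12)
  expect_equal(t_ab$p, t_ba$p, tolerance = 1e-12)
})

test_that("global comparison matches the hand-computed pooled t", {
  a <- c(1.2, 0.8, 1.1, 0.9, 1.3)
  b <- c(1.6, 1.8, 1.4, 1.7, 1.5)
  vals_a <- lapply(1:8, function(i) a); vals_b <- lapply(1:8, function(i) b)
  names(vals_a) <- names(vals_b) <-
    c("network_strength", "clustering_coefficient", "shortest_path_length",
      "small_worldness", "global_efficiency", "local_efficiency",
      "hierarchy", "assortativity")
  tab <- compare_global(make_global_list(vals_a, 5), make_global_list(vals_b, 5))
  or <- oracle_pooled_t(a, b)
  expect_equal(tab$statistic[1], or$t, tolerance = 1e-12)
  expect_equal(tab$p[1], or$p, tolerance = 1e-12)
})

make_nodal <- function(mat, regions) {
  # mat: subjects x regions values used for every metric
  lapply(seq_len(nrow(mat)), function(s) {
    structure(data.frame(region = regions, degree = 1, strength = mat[s, ],
                         clustering = mat[s, ], shortest_path_length = mat[s, ],
                         global_efficiency = mat[s, ],
                         local_efficiency = mat[s, ],
                         stringsAsFactors = FALSE),
              class = c("fn_nodal_metrics", "data.frame"))
  })
}

test_that("nodal comparison applies BH step-up within each metric family", {
  regions <- sprintf("r%d", 1:6)
  set.seed(4)
  ma <- matrix(rnorm(8 * 6), 8, 6)
  mb <- matrix(rnorm(8 * 6), 8, 6)
  mb[, 1:2] <- mb[, 1:2] + 3
  tab <- compare_nodal(make_nodal(ma, regions), make_nodal(mb, regions),
                       q = 0.05)
  one <- tab[tab$metric == "strength", ]
  expect_equal(one$p_adjusted, p.adjust(one$p, method = "BH"))
  # BH monotone: adjusted p preserves the raw ordering
  expect_equal(order(one$p), order(one$p_adjusted))
  # identical groups: no significant regions
  tab0 <- compare_nodal(make_nodal(ma, regions), make_nodal(ma, regions))
  expect_false(any(tab0$significant))
})

test_that("metric-covariate correlations recover planted relations", {
  set.seed(5)
  n <- 1000
  met <- data.frame(subject_id = sprintf("s%d", 1:n), m1 = rnorm(n))
  cov <- data.frame(subject_id = met$subject_id,
                    self = met$m1,
                    indep = rnorm(n))
  out <- correlate_metrics(met, cov)
  expect_equal(out$r[out$covariate == "self"], 1, tolerance = 1e-12)
  expect_lt(abs(out$r[out$covariate == "indep"]), 0.1)
  expect_equal(out$n, c(n, n))
  # missing covariates shrink n per pair; < 3 complete pairs flagged
  cov$self[1:(n - 2)] <- NA
  out2 <- correlate_metrics(met, cov)
  expect_true(is.na(out2$r[out2$covariate == "self"]))
  expect_equal(out2$n[out2$covariate == "self"], 2)
})

test_that("connection-class comparisons match the textbook t", {
  mk_classes <- function(strengths) {
    lapply(strengths, function(s) {
      structure(list(summary = data.frame(
        class = c("rich_club", "feeder", "local"),
        strength = c(s, 2 * s, 3 * s), degree = c(4, 6, 8),
        average_strength = c(s / 4, s / 3, 3 * s / 8),
        stringsAsFactors = FALSE)), class = "fn_edge_classes")
    })
  }
  a <- c(1.0, 1.2, 0.9, 1.1, 1.0)
  b <- c(1.5, 1.6, 1.4, 1.7, 1.5)
  tab <- compare_connection_classes(mk_classes(a), mk_classes(b))
  or <- oracle_pooled_t(a, b)
  got <- tab[tab$class == "rich_club" & tab$quantity == "strength", ]
  expect_equal(got$statistic, or$t, tolerance = 1e-12)
  expect_equal(got$p, or$p, tolerance = 1e-12)
  tab0 <- compare_connection_classes(mk_classes(a), mk_classes(a))
  expect_false(any(tab0$significant))
})

test_that("demographic test wrappers agree with the stats package", {
  set.seed(6)
  x <- rnorm(20); y <- rnorm(22, 0.5)
  expect_equal(demographic_t(x, y)$p,
               t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(demographic_mannwhitney(x, y)$p,
               wilcox.test(x, y, exact = FALSE)$p.value)
  tab <- matrix(c(20, 15, 10, 25), 2)
  expect_equal(demographic_chisq(tab)$p,
               chisq.test(tab, correct = FALSE)$p.value)
})
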
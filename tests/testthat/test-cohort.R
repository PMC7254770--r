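test_that("cohort bookkeeping, labelling and determinism", {
  spec <- cohort_spec(n_group_a = 5, n_group_b = 5, n_regions = 8,
                      n_volumes = 40, seed = 11)
  co <- generate_cohort(spec)
  expect_length(co$subjects, 10)
  grp <- vapply(co$subjects, `[[`, character(1), "group_label")
  expect_equal(sum(grp == "A"), 5)
  expect_equal(sum(grp == "B"), 5)
  expect_true(all(vapply(co$subjects, function(s) all(is.finite(s$values)),
                         logical(1))))
  co2 <- generate_cohort(spec)
  expect_identical(lapply(co$subjects, `[[`, "values"),
                   lapply(co2$subjects, `[[`, "values"))
  expect_identical(co$covariates, co2$covariates)
})

test_that("planted group-B edge raises the sample correlation by its delta", {
  spec <- cohort_spec(n_group_a = 200, n_group_b = 200, n_regions = 10,
                      n_volumes = 197,
                      community_assignment = rep(1:2, each = 5),
                      base_within_community_corr = 0.2,
                      base_between_community_corr = 0.05,
                      planted_edges = data.frame(i = 1, j = 6, delta = 0.3),
                      seed = 21)
  co <- generate_cohort(spec)
  grp <- vapply(co$subjects, `[[`, character(1), "group_label")
  r16 <- vapply(co$subjects, function(s) cor(s$values)[1, 6], numeric(1))
  diff <- mean(r16[grp == "B"]) - mean(r16[grp == "A"])
  expect_gt(diff, 0.25)
  expect_lt(diff, 0.35)
})

test_that("sample correlations of a large group converge to the latent matrix", {
  spec <- cohort_spec(n_group_a = 500, n_group_b = 0, n_regions = 8,
                      n_volumes = 120,
                      community_assignment = rep(1:2, each = 4),
                      base_within_community_corr = 0.4,
                      base_between_community_corr = 0.1,
                      ar1_coefficient = 0.3, seed = 31)
  co <- generate_cohort(spec)
  rbar <- Reduce(`+`, lapply(co$subjects, function(s) cor(s$values))) /
    length(co$subjects)
  expect_lt(max(abs(rbar - latent_correlation(spec, "A"))), 0.05)
})

test_that("invalid planted deltas are rejected naming the edge", {
  expect_error(
    cohort_spec(n_group_a = 2, n_group_b = 2, n_regions = 5, n_volumes = 10,
                base_within_community_corr = 0.8,
                community_assignment = rep(1L, 5),
                planted_edges = data.frame(i = 1, j = 2, delta = 0.5)),
    "\\(1, 2\\)")
  expect_error(cohort_spec(n_group_a = 2, n_group_b = 2, n_volumes = 1),
               "n_volumes")
  expect_error(
    cohort_spec(n_group_a = 2, n_group_b = 2, n_regions = 6,
                community_assignment = 1:3),
    "community")
})

test_that("band-pass filter kills DC, passes mid-band, attenuates stop-band", {
  n_t <- 197; tr <- 3
  tgrid <- (seq_len(n_t) - 1) * tr
  # constant series is removed entirely
  const <- matrix(5, n_t, 2)
  expect_lt(max(abs(bandpass_filter(const, 0.01, 0.1, tr_seconds = tr))),
            1e-8)
  amp_gain <- function(freq) {
    x <- matrix(sin(2 * pi * freq * tgrid), ncol = 1)
    y <- bandpass_filter(x, 0.01, 0.1, tr_seconds = tr)
    core <- 20:178  # avoid filter edge effects
    b <- cbind(sin(2 * pi * freq * tgrid[core]),
               cos(2 * pi * freq * tgrid[core]))
    fit <- lm.fit(b, y[core, 1])
    sqrt(sum(fit$coefficients^2))
  }
  expect_gte(amp_gain(0.05), 0.9)
  expect_lte(amp_gain(0.16), 0.2)
  expect_error(bandpass_filter(const, 0.01, 0.2, tr_seconds = tr), "Nyquist")
})

test_that("default atlas has 90 uniquely labelled regions; toy atlases work", {
  at <- make_default_atlas()
  expect_equal(at$n_regions, 90)
  expect_equal(anyDuplicated(at$labels), 0)
  d <- centroid_distances(at)
  expect_true(all(d[upper.tri(d)] > 0))
  # a 3-region atlas substitutes everywhere downstream
  toy <- toy_atlas()
  bins <- distance_bins(toy)
  ed <- data.frame(region_i = "X", region_j = "Y")
  st <- stratify_edges(ed, bins)
  expect_equal(st$edges$distance_mm, 5)
})

test_that("planted covariates hit their target correlation", {
  spec <- cohort_spec(
    n_group_a = 0, n_group_b = 150, n_regions = 8, n_volumes = 80,
    community_assignment = rep(1:2, each = 4),
    covariate_models = list(list(name = "biom", metric = "strength",
                                 region = 2, target_correlation = -0.5,
                                 group_scope = "B")),
    seed = 41)
  co <- generate_cohort(spec)
  s2 <- vapply(co$subjects, function(s) {
    sum(threshold_network(correlation_matrix(s))$weights[2, ])
  }, numeric(1))
  r <- cor(s2, co$covariates$biom)
  expect_lt(abs(r - (-0.5)), 0.15)
})
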
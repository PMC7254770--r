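#' Specify a two-group synthetic cohort
#'
#' Defines the generative model for a synthetic resting-state cohort: two
#' groups of subjects, each subject a multivariate time series over atlas
#' regions. Region signals are drawn from a modular (community-structured)
#' latent correlation matrix, temporally coloured by a per-region AR(1)
#' process. Group B additionally receives planted correlation increments on
#' designated edges, and covariates can be planted with a target correlation
#' to a subject-level nodal metric.
#'
#' Defaults emulate an elderly two-group resting-state study: 64 vs 66
#' subjects, 90 regions, 197 volumes at TR = 3 s.
#'
#' @param n_group_a,n_group_b subjects per group.
#' @param n_regions number of atlas regions (default 90).
#' @param n_volumes time points per subject (default 197).
#' @param tr_seconds repetition time in seconds (default 3).
#' @param community_assignment integer vector of length `n_regions` mapping
#'   each region to a community; `NULL` uses [default_communities()].
#' @param base_within_community_corr latent correlation within a community.
#' @param base_between_community_corr latent correlation between communities.
#' @param planted_edges data frame with columns `i`, `j`, `delta`: latent
#'   correlation increments applied to group B only (region indices).
#' @param ar1_coefficient AR(1) temporal autocorrelation in `[0, 1)`.
#' @param covariate_models list of lists with fields `name`, `metric`
#'   (one of `"strength"`, `"global_efficiency"`, `"local_efficiency"`,
#'   `"clustering"`, `"shortest_path_length"`), `region` (index or label),
#'   `target_correlation`, `group_scope` (`"A"`, `"B"` or `"all"`).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return object of class `fn_cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 64, n_group_b = 66,
                        n_regions = 90, n_volumes = 197, tr_seconds = 3,
                        community_assignment = NULL,
                        base_within_community_corr = 0.35,
                        base_between_community_corr = 0.10,
                        planted_edges = NULL,
                        ar1_coefficient = 0.3,
                        covariate_models = list(),
                        seed = 1L) {
  if (!is_count(n_group_a) || !is_count(n_group_b)) {
    stopf("group sizes must be non-negative integers")
  }
  if (!is_count(n_regions) || n_regions < 2) stopf("n_regions must be >= 2")
  if (!is_count(n_volumes) || n_volumes < 2) {
    stopf("n_volumes must be an integer >= 2")
  }
  if (tr_seconds <= 0) stopf("tr_seconds must be positive")
  if (is.null(community_assignment)) {
    community_assignment <- default_communities(n_regions)
  }
  community_assignment <- as.integer(community_assignment)
  if (length(community_assignment) != n_regions ||
      anyNA(community_assignment)) {
    stopf("community_assignment must map every one of the %d regions exactly once",
          n_regions)
  }
  if (base_within_community_corr < 0 || base_within_community_corr >= 1 ||
      base_between_community_corr < 0 || base_between_community_corr >= 1) {
    stopf("base correlations must lie in [0, 1)")
  }
  if (ar1_coefficient < 0 || ar1_coefficient >= 1) {
    stopf("ar1_coefficient must lie in [0, 1)")
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    if (!all(c("i", "j", "delta") %in% names(planted_edges))) {
      stopf("planted_edges needs columns i, j, delta")
    }
    if (any(planted_edges$i == planted_edges$j) ||
        any(planted_edges$i < 1 | planted_edges$i > n_regions) ||
        any(planted_edges$j < 1 | planted_edges$j > n_regions)) {
      stopf("planted edge indices must be distinct regions in 1..%d", n_regions)
    }
  }
  for (cm in covariate_models) {
    need <- c("name", "metric", "region", "target_correlation", "group_scope")
    if (!all(need %in% names(cm))) {
      stopf("each covariate model needs fields: %s", paste(need, collapse = ", "))
    }
    if (abs(cm$target_correlation) > 1) {
      stopf("covariate target correlation must be in [-1, 1]")
    }
  }
  spec <- list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_regions = as.integer(n_regions), n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds,
    community_assignment = community_assignment,
    base_within_community_corr = base_within_community_corr,
    base_between_community_corr = base_between_community_corr,
    planted_edges = planted_edges,
    ar1_coefficient = ar1_coefficient,
    covariate_models = covariate_models,
    seed = as.integer(seed)
  )
  # fail early if the planted deltas break the latent correlation matrix
  latent_correlation(spec, group = "B")
  structure(spec, class = "fn_cohort_spec")
}

#' Default community assignment for a cohort
#'
#' Six communities; for 90 regions, community 1 is a DMN-like set of 18
#' regions (medial frontal, cingulate, medial temporal including the
#' parahippocampal gyri, precuneus, angular) matching the bundled atlas
#' ordering, the rest split evenly. For other sizes, regions are split into
#' up to six contiguous blocks.
#'
#' @param n_regions number of regions.
#' @return integer vector of community ids.
#' @export
default_communities <- function(n_regions = 90) {
  if (n_regions == 90) {
    comm <- rep(0L, 90)
    comm[dmn_region_indices()] <- 1L
    rest <- which(comm == 0L)
    comm[rest] <- 2L + (seq_along(rest) - 1L) %% 5L
    comm
  } else {
    k <- min(6L, n_regions)
    as.integer(cut(seq_len(n_regions), breaks = k, labels = FALSE))
  }
}

# indices of DMN-like regions in the bundled 90-region atlas ordering
# (SFGmed, ORBsupmed, ACG, PCG, HIP, PHG, PCUN, ANG, both hemispheres,
#  plus REC for a medial-frontal anchor)
dmn_region_indices <- function() {
  stems <- c("SFGmed", "ORBsupmed", "REC", "ACG", "PCG", "HIP", "PHG",
             "PCUN", "ANG")
  at <- make_default_atlas()
  idx <- unlist(lapply(stems, function(s) {
    which(at$labels %in% paste0(s, c(".L", ".R")))
  }))
  sort(idx)
}

#' Latent correlation matrix implied by a cohort spec
#'
#' Builds the block community correlation matrix, applies group-B planted
#' deltas, and projects to the nearest positive semi-definite correlation
#' matrix by eigenvalue clipping if the deltas break semi-definiteness. The
#' maximum absolute entry change introduced by the projection is attached
#' as attribute `psd_projection_deviation`.
#'
#' @param spec `fn_cohort_spec` (or plain list with the same fields).
#' @param group `"A"` or `"B"`.
#' @return correlation matrix (n_regions x n_regions).
#' @export
latent_correlation <- function(spec, group = c("A", "B")) {
  group <- match.arg(group)
  comm <- spec$community_assignment
  n <- spec$n_regions
  same <- outer(comm, comm, "==")
  sigma <- ifelse(same, spec$base_within_community_corr,
                  spec$base_between_community_corr)
  diag(sigma) <- 1
  if (group == "B" && !is.null(spec$planted_edges)) {
    pe <- spec$planted_edges
    for (r in seq_len(nrow(pe))) {
      i <- pe$i[r]; j <- pe$j[r]
      v <- sigma[i, j] + pe$delta[r]
      if (abs(v) >= 1) {
        stopf("planted delta on edge (%d, %d) gives invalid latent correlation %.3f",
              i, j, v)
      }
      sigma[i, j] <- sigma[j, i] <- v
    }
  }
  ev <- eigen(sigma, symmetric = TRUE)
  dev <- 0
  if (min(ev$values) < 1e-10) {
    vals <- pmax(ev$values, 1e-8)
    fixed <- ev$vectors %*% (vals * t(ev$vectors))
    fixed <- stats::cov2cor(fixed)
    dev <- max(abs(fixed - sigma))
    sigma <- fixed
  }
  attr(sigma, "psd_projection_deviation") <- dev
  sigma
}

#' Generate a synthetic cohort
#'
#' Draws every subject's region x time signal from the spec's latent
#' correlation (group B with planted deltas), colours it with a per-region
#' AR(1) process (stationary via burn-in), and generates planted covariates
#' by the conditional-normal construction against each subject's realized
#' target metric. A pure function of `(spec, seed)`.
#'
#' @param spec `fn_cohort_spec`.
#' @return object of class `fn_cohort`: list with `subjects` (list of
#'   `fn_timeseries`), `covariates` (data frame, one row per subject;
#'   missing outside a model's group scope), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fn_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_regions
    labels <- if (n == 90) make_default_atlas()$labels else
      sprintf("R%02d", seq_len(n))
    chol_a <- chol(latent_correlation(spec, "A"))
    chol_b <- chol(latent_correlation(spec, "B"))
    burn <- 50L
    tt <- spec$n_volumes + burn
    phi <- spec$ar1_coefficient
    gen_one <- function(id, grp, ch) {
      z <- matrix(stats::rnorm(tt * n), tt, n)
      e <- z %*% ch
      y <- if (phi > 0) {
        apply(e, 2, function(col) {
          stats::filter(col, phi, method = "recursive")
        })
      } else {
        e
      }
      y <- y[(burn + 1):tt, , drop = FALSE]
      colnames(y) <- labels
      structure(list(subject_id = id, group_label = grp, values = y,
                     tr_seconds = spec$tr_seconds, region_labels = labels),
                class = "fn_timeseries")
    }
    ids_a <- sprintf("A%03d", seq_len(spec$n_group_a))
    ids_b <- sprintf("B%03d", seq_len(spec$n_group_b))
    subjects <- c(
      lapply(ids_a, gen_one, grp = "A", ch = chol_a),
      lapply(ids_b, gen_one, grp = "B", ch = chol_b)
    )
    covs <- data.frame(
      subject_id = c(ids_a, ids_b),
      group = c(rep("A", spec$n_group_a), rep("B", spec$n_group_b)),
      stringsAsFactors = FALSE
    )
    for (cm in spec$covariate_models) {
      covs[[cm$name]] <- plant_covariate(subjects, covs$group, cm, labels)
    }
    structure(list(subjects = subjects, covariates = covs, spec = spec),
              class = "fn_cohort")
  })
}

# covariate = rho * z(metric) + sqrt(1 - rho^2) * noise within group scope
plant_covariate <- function(subjects, groups, cm, labels) {
  scope <- if (identical(cm$group_scope, "all")) rep(TRUE, length(subjects))
           else groups == cm$group_scope
  region <- cm$region
  if (is.character(region)) {
    region <- match(region, labels)
    if (is.na(region)) stopf("covariate model region '%s' not in atlas", cm$region)
  }
  metric <- vapply(subjects[scope], function(s) {
    net <- threshold_network(correlation_matrix(s))
    nodal_metric_value(net, cm$metric, region)
  }, numeric(1))
  z <- as.vector(scale(metric))
  if (anyNA(z)) z <- rep(0, length(metric))  # degenerate: constant metric
  rho <- cm$target_correlation
  val <- rho * z + sqrt(1 - rho^2) * stats::rnorm(length(z))
  out <- rep(NA_real_, length(subjects))
  out[scope] <- val
  out
}

# single nodal metric for one region (cheap path for strength)
nodal_metric_value <- function(net, metric, region) {
  if (identical(metric, "strength")) {
    return(sum(net$weights[region, ]))
  }
  nm <- nodal_metrics(net)
  col <- switch(metric,
    global_efficiency = nm$global_efficiency,
    local_efficiency = nm$local_efficiency,
    clustering = nm$clustering,
    shortest_path_length = nm$shortest_path_length,
    stopf("unknown covariate target metric '%s'", metric)
  )
  col[region]
}

#' Band-pass filter a regional time series
#'
#' Zero-phase (forward-backward) Butterworth filter of order 4; columns are
#' demeaned first, so the DC component is removed exactly.
#'
#' @param ts an `fn_timeseries` or a plain time x regions matrix.
#' @param low_hz,high_hz passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < ` Nyquist (`1 / (2 * tr_seconds)`).
#' @param tr_seconds sampling interval; taken from `ts` when it is an
#'   `fn_timeseries`.
#' @param order filter order (default 4).
#' @return filtered object of the same type and shape.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.1,
                            tr_seconds = NULL, order = 4) {
  is_obj <- inherits(ts, "fn_timeseries")
  values <- if (is_obj) ts$values else as.matrix(ts)
  if (is_obj) tr_seconds <- ts$tr_seconds
  if (is.null(tr_seconds)) stopf("tr_seconds required for matrix input")
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stopf("need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyq) {
    stopf("high_hz = %g Hz is at or above Nyquist (%.4g Hz at TR = %g s)",
          high_hz, nyq, tr_seconds)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  centered <- scale(values, center = TRUE, scale = FALSE)
  filtered <- apply(centered, 2, function(col) {
    signal::filtfilt(bf, col)
  })
  dimnames(filtered) <- dimnames(values)
  if (is_obj) {
    ts$values <- filtered
    ts
  } else {
    filtered
  }
}

#' @export
print.fn_cohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, character(1), "group_label")
  cat(sprintf("Synthetic cohort: %d subjects (A: %d, B: %d), %d regions, %d volumes, TR %g s\n",
              length(x$subjects), sum(grp == "A"), sum(grp == "B"),
              x$spec$n_regions, x$spec$n_volumes, x$spec$tr_seconds))
  extra <- setdiff(names(x$covariates), c("subject_id", "group"))
  if (length(extra)) cat("  covariates:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.fn_timeseries <- function(x, ...) {
  cat(sprintf("Time series %s (group %s): %d volumes x %d regions, TR %g s\n",
              x$subject_id, x$group_label, nrow(x$values), ncol(x$values),
              x$tr_seconds))
  invisible(x)
}
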
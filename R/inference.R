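# Group comparison tables and metric-covariate correlations.

# pooled- or Welch-variance two-sample t on two numeric vectors
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    return(list(t = NA_real_, p = NA_real_))
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = NA_real_, p = NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

comparison_row <- function(name, a, b, var_equal) {
  ts <- two_sample_t(a, b, var_equal)
  data.frame(metric = name,
             mean_a = mean(a, na.rm = TRUE), sd_a = stats::sd(a, na.rm = TRUE),
             mean_b = mean(b, na.rm = TRUE), sd_b = stats::sd(b, na.rm = TRUE),
             statistic = ts$t, p = ts$p, stringsAsFactors = FALSE)
}

#' Compare global network metrics between two groups
#'
#' Per-metric two-sample t-tests (pooled variance by default), without
#' multiplicity adjustment.
#'
#' @param group_a,group_b lists of `fn_global_metrics` (one per subject).
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled (Student, default) vs Welch variance.
#' @return data frame of class `fn_comparison` with group means/SDs,
#'   t statistic, raw p, adjusted p (= raw; `adjustment = "none"`) and a
#'   significance flag.
#' @export
compare_global <- function(group_a, group_b, alpha = 0.05, var_equal = TRUE) {
  da <- do.call(rbind, lapply(group_a, as.data.frame))
  db <- do.call(rbind, lapply(group_b, as.data.frame))
  if (nrow(da) < 2 || nrow(db) < 2) stopf("need at least 2 subjects per group")
  out <- do.call(rbind, lapply(names(da), function(m) {
    comparison_row(m, da[[m]], db[[m]], var_equal)
  }))
  out$p_adjusted <- out$p
  out$significant <- !is.na(out$p) & out$p < alpha
  structure(out, class = c("fn_comparison", "data.frame"),
            adjustment = "none", alpha = alpha)
}

#' Compare nodal metrics between two groups with FDR correction
#'
#' Per-region, per-metric two-sample t-tests; Benjamini-Hochberg step-up
#' adjustment applied within each metric family (one family = the N
#' regional tests of one metric).
#'
#' @param group_a,group_b lists of `fn_nodal_metrics` (one per subject).
#' @param q FDR level (default 0.05).
#' @param metrics metric columns to compare.
#' @param var_equal pooled (default) vs Welch variance.
#' @return data frame of class `fn_comparison` with columns `metric`,
#'   `region`, group means/SDs, `statistic`, `p`, `p_adjusted`,
#'   `significant`.
#' @export
compare_nodal <- function(group_a, group_b, q = 0.05,
                          metrics = c("strength", "clustering",
                                      "shortest_path_length",
                                      "global_efficiency", "local_efficiency"),
                          var_equal = TRUE) {
  if (!(q > 0 && q < 1)) stopf("q must lie in (0, 1)")
  regions <- group_a[[1]]$region
  stack <- function(group, m) {
    vapply(group, function(nm) nm[[m]], numeric(length(regions)))
  }
  out <- do.call(rbind, lapply(metrics, function(m) {
    ma <- stack(group_a, m); mb <- stack(group_b, m)
    rows <- do.call(rbind, lapply(seq_along(regions), function(i) {
      r <- comparison_row(m, ma[i, ], mb[i, ], var_equal)
      r$region <- regions[i]
      r
    }))
    rows$p_adjusted <- stats::p.adjust(rows$p, method = "BH")
    rows
  }))
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < q
  out <- out[, c("metric", "region", "mean_a", "sd_a", "mean_b", "sd_b",
                 "statistic", "p", "p_adjusted", "significant")]
  structure(out, class = c("fn_comparison", "data.frame"),
            adjustment = "FDR", alpha = q)
}

#' Compare rich-club / feeder / local connection-class summaries
#'
#' Two-sample t-tests (uncorrected) on the strength, degree and average
#' strength of each connection class.
#'
#' @param group_a,group_b lists of `fn_edge_classes` (one per subject).
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled (default) vs Welch variance.
#' @return data frame of class `fn_comparison` with one row per
#'   (class, quantity) pair.
#' @export
compare_connection_classes <- function(group_a, group_b, alpha = 0.05,
                                       var_equal = TRUE) {
  pull <- function(group, cl, what) {
    vapply(group, function(ec) {
      ec$summary[[what]][ec$summary$class == cl]
    }, numeric(1))
  }
  classes <- c("rich_club", "feeder", "local")
  quantities <- c("strength", "degree", "average_strength")
  out <- do.call(rbind, lapply(classes, function(cl) {
    do.call(rbind, lapply(quantities, function(qt) {
      r <- comparison_row(paste(cl, qt, sep = "."),
                          pull(group_a, cl, qt), pull(group_b, cl, qt),
                          var_equal)
      r$class <- cl; r$quantity <- qt
      r
    }))
  }))
  out$p_adjusted <- out$p
  out$significant <- !is.na(out$p) & out$p < alpha
  structure(out, class = c("fn_comparison", "data.frame"),
            adjustment = "none", alpha = alpha)
}

#' Correlate network metrics with covariates
#'
#' Pairwise-complete Pearson correlations with two-sided p-values;
#' subjects are aligned by `subject_id`, and missing covariate values are
#' simply dropped (so biomarker subsamples shrink `n` per pair).
#'
#' @param metrics data frame with `subject_id` plus one column per metric.
#' @param covariates data frame with `subject_id` plus covariate columns.
#' @param pairs data frame with columns `metric`, `covariate` naming the
#'   requested pairs; `NULL` crosses every metric with every covariate.
#' @return data frame of class `fn_correlations` with `metric`,
#'   `covariate`, `r`, `p`, `n`; pairs with fewer than 3 complete
#'   observations are flagged with `NA`.
#' @export
correlate_metrics <- function(metrics, covariates, pairs = NULL) {
  merged <- merge(metrics, covariates, by = "subject_id")
  met_cols <- setdiff(names(metrics), "subject_id")
  cov_cols <- setdiff(names(covariates), c("subject_id", "group"))
  if (is.null(pairs)) {
    pairs <- expand.grid(metric = met_cols, covariate = cov_cols,
                         stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    m <- pairs$metric[k]; cv <- pairs$covariate[k]
    x <- merged[[m]]; y <- merged[[cv]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      return(data.frame(metric = m, covariate = cv, r = NA_real_,
                        p = NA_real_, n = sum(ok), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(metric = m, covariate = cv, r = unname(ct$estimate),
               p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  }))
  structure(out, class = c("fn_correlations", "data.frame"))
}

#' Demographic-style comparisons: t, Mann-Whitney and chi-squared
#'
#' Thin wrappers for comparing per-subject covariates between groups:
#' numeric covariates by two-sample t-test or Mann-Whitney (Wilcoxon
#' rank-sum), categorical covariates by the chi-squared test.
#'
#' @param x,y numeric vectors (one per group), or for `chisq` two factors /
#'   a contingency table.
#' @param var_equal pooled (default) vs Welch variance for the t-test.
#' @return list with `statistic` and `p`.
#' @name demographic_tests
NULL

#' @rdname demographic_tests
#' @export
demographic_t <- function(x, y, var_equal = TRUE) {
  r <- two_sample_t(x, y, var_equal)
  list(statistic = r$t, p = r$p)
}

#' @rdname demographic_tests
#' @export
demographic_mannwhitney <- function(x, y) {
  ht <- stats::wilcox.test(x, y, exact = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @rdname demographic_tests
#' @export
demographic_chisq <- function(x, y = NULL) {
  tab <- if (is.table(x) || is.matrix(x)) as.table(x) else table(x, y)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @export
print.fn_comparison <- function(x, ...) {
  adj <- attr(x, "adjustment")
  cat(sprintf("Group comparison (%s adjustment, level %g): %d tests, %d significant\n",
              adj, attr(x, "alpha"), nrow(x), sum(x$significant, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}
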
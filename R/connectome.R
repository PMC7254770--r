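#' Pearson connectivity matrix of a regional time series
#'
#' Sample Pearson correlation between every pair of regional mean time
#' series, with two-sided p-values from the t distribution with
#' `n_timepoints - 2` degrees of freedom.
#'
#' @param ts an `fn_timeseries` or a plain time x regions matrix (with
#'   column names as region labels).
#' @return object of class `fn_connectivity`: list with `r` (correlations,
#'   unit diagonal), `p` (two-sided p-values, `NA` diagonal),
#'   `n_timepoints`, `region_labels`.
#' @export
correlation_matrix <- function(ts) {
  values <- if (inherits(ts, "fn_timeseries")) ts$values else as.matrix(ts)
  n_t <- nrow(values)
  if (n_t < 3) stopf("need at least 3 time points for correlation tests")
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(values)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stopf("zero-variance region(s): %s", paste(bad, collapse = ", "))
  }
  r <- stats::cor(values)
  r[r > 1] <- 1
  r[r < -1] <- -1
  tstat <- r * sqrt((n_t - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n_t - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(p) <- NA
  labels <- colnames(values)
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(ncol(values)))
  dimnames(r) <- dimnames(p) <- list(labels, labels)
  structure(list(r = r, p = p, n_timepoints = n_t, region_labels = labels),
            class = "fn_connectivity")
}

#' Wrap a precomputed correlation matrix as a connectivity object
#'
#' For workflows starting from correlation matrices rather than time
#' series; `n_timepoints` is required to form the p-values.
#'
#' @param r symmetric correlation matrix with unit diagonal.
#' @param n_timepoints number of time points the correlations came from.
#' @return `fn_connectivity`.
#' @export
as_connectivity <- function(r, n_timepoints) {
  r <- as.matrix(r)
  check_symmetric(r, "r")
  if (max(abs(r)) > 1 + 1e-10) stopf("correlations must lie in [-1, 1]")
  if (max(abs(diag(r) - 1)) > 1e-10) stopf("correlation diagonal must be 1")
  if (!is_count(n_timepoints) || n_timepoints < 3) {
    stopf("n_timepoints must be an integer >= 3")
  }
  tstat <- r * sqrt((n_timepoints - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n_timepoints - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(p) <- NA
  labels <- rownames(r)
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(nrow(r)))
  dimnames(r) <- dimnames(p) <- list(labels, labels)
  structure(list(r = r, p = p, n_timepoints = as.integer(n_timepoints),
                 region_labels = labels),
            class = "fn_connectivity")
}

#' Bonferroni-threshold a connectivity matrix into a weighted network
#'
#' Retains edge (i, j) iff `p_ij < alpha / n_tests`; by default `n_tests`
#' is the full pair count `N(N-1)/2` (4005 for 90 regions). Retained
#' correlations become edge weights under the chosen negative-edge policy.
#'
#' @param conn `fn_connectivity`.
#' @param alpha significance level before correction (default 0.05).
#' @param n_tests Bonferroni denominator; default `N(N-1)/2`.
#' @param negative_policy how to weight retained negative correlations:
#'   `"positive"` (default; drop them, weight = r for positive edges),
#'   `"absolute"` (weight = |r|), or `"keep-signed"` (weight = r; the
#'   topological metrics then refuse the network).
#' @return object of class `fn_network`: list with `weights` (symmetric,
#'   zero diagonal), `adjacency` (binary, `weights != 0`), `region_labels`,
#'   `provenance` (alpha, n_tests, per-edge threshold, policy).
#' @export
threshold_network <- function(conn, alpha = 0.05, n_tests = NULL,
                              negative_policy = c("positive", "absolute",
                                                  "keep-signed")) {
  stopifnot(inherits(conn, "fn_connectivity"))
  negative_policy <- match.arg(negative_policy)
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must lie in (0, 1)")
  n <- nrow(conn$r)
  if (is.null(n_tests)) n_tests <- n * (n - 1) / 2
  thr <- alpha / n_tests
  keep <- !is.na(conn$p) & conn$p < thr
  w <- ifelse(keep, conn$r, 0)
  w <- switch(negative_policy,
    "positive" = pmax(w, 0),
    "absolute" = abs(w),
    "keep-signed" = w
  )
  diag(w) <- 0
  dimnames(w) <- dimnames(conn$r)
  weighted_network(w, provenance = list(alpha = alpha, n_tests = n_tests,
                                        edge_threshold = thr,
                                        negative_policy = negative_policy))
}

#' Construct a weighted network from a weight matrix
#'
#' @param weights symmetric weight matrix with zero diagonal.
#' @param provenance optional list recording how the weights were obtained.
#' @return `fn_network`.
#' @export
weighted_network <- function(weights, provenance = list()) {
  weights <- as.matrix(weights)
  check_symmetric(weights, "weights")
  if (!all(is.finite(weights))) stopf("weights must be finite")
  if (any(diag(weights) != 0)) stopf("weight diagonal must be zero")
  labels <- rownames(weights)
  if (is.null(labels)) {
    labels <- sprintf("R%02d", seq_len(nrow(weights)))
    dimnames(weights) <- list(labels, labels)
  }
  structure(list(weights = weights,
                 adjacency = (weights != 0) * 1L,
                 region_labels = labels,
                 provenance = provenance),
            class = "fn_network")
}

#' Binary degree of every node
#' @param net `fn_network`.
#' @return integer vector of degrees named by region.
#' @export
network_degree <- function(net) {
  stopifnot(inherits(net, "fn_network"))
  d <- rowSums(net$adjacency)
  names(d) <- net$region_labels
  d
}

#' Edge list of a weighted network
#'
#' One undirected edge per row, pairs in lexicographic label order.
#' @param net `fn_network`.
#' @return data frame with `region_i`, `region_j`, `weight`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "fn_network"))
  w <- net$weights
  p <- upper_pairs(nrow(w))
  keep <- w[cbind(p[, 1], p[, 2])] != 0
  li <- net$region_labels[p[keep, 1]]
  lj <- net$region_labels[p[keep, 2]]
  swap <- li > lj
  tmp <- li[swap]; li[swap] <- lj[swap]; lj[swap] <- tmp
  out <- data.frame(region_i = li, region_j = lj,
                    weight = w[cbind(p[keep, 1], p[keep, 2])],
                    stringsAsFactors = FALSE)
  out[order(out$region_i, out$region_j), , drop = FALSE]
}

#' @export
print.fn_connectivity <- function(x, ...) {
  cat(sprintf("Connectivity matrix: %d regions, %d time points\n",
              nrow(x$r), x$n_timepoints))
  up <- x$r[upper.tri(x$r)]
  cat(sprintf("  r range [%.3f, %.3f], mean %.3f\n",
              min(up), max(up), mean(up)))
  invisible(x)
}

#' @export
print.fn_network <- function(x, ...) {
  ne <- sum(x$adjacency) / 2
  n <- nrow(x$weights)
  cat(sprintf("Weighted network: %d regions, %d edges (density %.3f)\n",
              n, ne, ne / (n * (n - 1) / 2)))
  if (length(x$provenance)) {
    pv <- x$provenance
    if (!is.null(pv$alpha)) {
      cat(sprintf("  threshold: p < %g / %d = %.3g, policy '%s'\n",
                  pv$alpha, pv$n_tests, pv$edge_threshold, pv$negative_policy))
    }
  }
  invisible(x)
}
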
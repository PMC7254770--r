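# Weighted topological metrics.
#
# Conventions (fixed package-wide):
#  - edge length for shortest paths = 1 / weight (stronger correlation =
#    shorter functional distance);
#  - weighted clustering = geometric mean of triangle weights, weights
#    rescaled by the network maximum (bounded in [0, 1]);
#  - disconnected pairs contribute 0 to efficiencies; nodal / global path
#    length averages finite distances only, with the unreachable-pair
#    count reported alongside.

# all-pairs shortest path distances on lengths 1/w
shortest_distances <- function(w) {
  n <- nrow(w)
  if (!any(w != 0)) {
    d <- matrix(Inf, n, n); diag(d) <- 0
    return(d)
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

# Onnela-style weighted clustering per node
weighted_clustering <- function(w) {
  n <- nrow(w)
  k <- rowSums(w != 0)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  cw <- (w / mx)^(1 / 3)
  tri <- diag(cw %*% cw %*% cw)
  denom <- k * (k - 1)
  out <- ifelse(denom > 0, tri / denom, 0)
  out
}

# mean inverse distance over ordered pairs (global efficiency of a matrix)
efficiency_of <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  d <- shortest_distances(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

check_nonnegative <- function(net) {
  if (any(net$weights < 0)) {
    stopf(paste("network has negative weights; topological metrics require",
                "nonnegative weights (use negative_policy 'positive' or",
                "'absolute' when thresholding)"))
  }
}

#' Nodal topological metrics of a weighted network
#'
#' Computes, per region: binary degree, strength (sum of incident weights),
#' weighted clustering coefficient, nodal shortest path length (mean finite
#' distance to other nodes, on edge lengths 1/w), nodal global efficiency
#' (mean inverse distance), and nodal local efficiency (global efficiency
#' of the subgraph induced by the node's neighbours). Isolated nodes get
#' strength, clustering and both efficiencies 0 and path length `NA`.
#'
#' @param net `fn_network` with nonnegative weights.
#' @return data frame of class `fn_nodal_metrics` with columns `region`,
#'   `degree`, `strength`, `clustering`, `shortest_path_length`,
#'   `global_efficiency`, `local_efficiency`.
#' @export
nodal_metrics <- function(net) {
  stopifnot(inherits(net, "fn_network"))
  check_nonnegative(net)
  w <- net$weights
  n <- nrow(w)
  k <- rowSums(w != 0)
  s <- rowSums(w)
  cc <- weighted_clustering(w)
  d <- shortest_distances(w)
  inv <- 1 / d
  diag(inv) <- NA
  inv[!is.finite(inv) & !is.na(inv)] <- 0
  e_glob <- rowSums(inv, na.rm = TRUE) / (n - 1)
  fin <- d
  diag(fin) <- NA
  fin[!is.finite(fin)] <- NA
  l <- rowMeans(fin, na.rm = TRUE)
  l[!is.finite(l)] <- NA
  e_loc <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    efficiency_of(w[nb, nb, drop = FALSE])
  }, numeric(1))
  structure(
    data.frame(region = net$region_labels, degree = k, strength = s,
               clustering = cc, shortest_path_length = l,
               global_efficiency = e_glob, local_efficiency = e_loc,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("fn_nodal_metrics", "data.frame")
  )
}

#' Global topological metrics of a weighted network
#'
#' The eight whole-network properties: network strength (mean nodal
#' strength by default), clustering coefficient, shortest path length,
#' small-worldness (with its gamma/lambda components against
#' degree-and-weight preserving rewired nulls), global efficiency, local
#' efficiency, hierarchy and assortativity.
#'
#' Hierarchy beta is the negated slope of the `log c_i ~ log k_i`
#' regression (convention `c ~ k^-beta`), over nodes with `k > 1` and
#' `c > 0`. Assortativity is the Pearson correlation of endpoint degrees
#' over edges. Undefined quantities (fewer than 2 edges, degenerate
#' regressions) are reported as `NA`, never fabricated.
#'
#' @param net `fn_network` with nonnegative weights.
#' @param n_null number of rewired null networks for gamma/lambda/sigma
#'   (default 100).
#' @param seed seed for the null ensemble.
#' @param strength_summary `"mean"` (default) or `"sum"` of nodal strengths.
#' @param null_networks optional list of `fn_network` to use as the null
#'   ensemble instead of generating one (e.g. identity nulls in tests).
#' @return list of class `fn_global_metrics`.
#' @export
global_metrics <- function(net, n_null = 100, seed = 1,
                           strength_summary = c("mean", "sum"),
                           null_networks = NULL) {
  stopifnot(inherits(net, "fn_network"))
  check_nonnegative(net)
  strength_summary <- match.arg(strength_summary)
  nm <- nodal_metrics(net)
  n <- nrow(net$weights)
  d <- shortest_distances(net$weights)
  up <- d[upper.tri(d)]
  unreachable <- sum(!is.finite(up))
  sp <- if (strength_summary == "mean") mean(nm$strength) else sum(nm$strength)
  cp <- mean(nm$clustering)
  lp <- if (all(is.na(nm$shortest_path_length))) NA_real_
        else mean(nm$shortest_path_length, na.rm = TRUE)
  eglob <- efficiency_of(net$weights)
  eloc <- mean(nm$local_efficiency)

  n_edges <- sum(net$adjacency) / 2
  gamma <- lambda <- sigma <- NA_real_
  if (n_edges >= 2 && n_null >= 1) {
    if (is.null(null_networks)) {
      null_networks <- lapply(seq_len(n_null), function(r) {
        rewire_null(net, seed = seed + r)
      })
    }
    null_cp <- vapply(null_networks, function(g) {
      mean(weighted_clustering(g$weights))
    }, numeric(1))
    null_lp <- vapply(null_networks, function(g) {
      dg <- shortest_distances(g$weights)
      diag(dg) <- NA
      dg[!is.finite(dg)] <- NA
      li <- rowMeans(dg, na.rm = TRUE)
      mean(li[is.finite(li)])
    }, numeric(1))
    gamma <- cp / mean(null_cp)
    lambda <- lp / mean(null_lp)
    sigma <- gamma / lambda
  }

  hierarchy <- NA_real_
  ok <- nm$degree > 1 & nm$clustering > 0
  hierarchy_excluded <- sum(!ok)
  if (sum(ok) >= 3 && stats::sd(log(nm$degree[ok])) > 0) {
    fit <- stats::lm(log(nm$clustering[ok]) ~ log(nm$degree[ok]))
    hierarchy <- -unname(stats::coef(fit)[2])
  }

  assort <- NA_real_
  if (n_edges >= 2) {
    p <- upper_pairs(n)
    onedge <- net$weights[cbind(p[, 1], p[, 2])] != 0
    ki <- nm$degree[p[onedge, 1]]
    kj <- nm$degree[p[onedge, 2]]
    x <- c(ki, kj); y <- c(kj, ki)
    if (stats::sd(x) > 0) assort <- stats::cor(x, y)
  }

  structure(list(
    network_strength = sp, clustering_coefficient = cp,
    shortest_path_length = lp, gamma = gamma, lambda = lambda,
    small_worldness = sigma, global_efficiency = eglob,
    local_efficiency = eloc, hierarchy = hierarchy,
    assortativity = assort,
    unreachable_pairs = unreachable,
    hierarchy_excluded_nodes = hierarchy_excluded,
    null_model_summary = list(n_null = if (n_edges >= 2) n_null else 0L,
                              seed = seed),
    strength_summary = strength_summary
  ), class = "fn_global_metrics")
}

#' Degree- and weight-preserving rewired null network
#'
#' Maslov-Sneppen double-edge swaps: repeatedly picks two edges (a,b),
#' (c,d) and rewires them to (a,d), (c,b) when that creates no self-loop or
#' duplicate edge, carrying each edge's weight with it. The binary degree
#' sequence and the weight multiset are preserved exactly; connectedness is
#' not enforced. `10 * |E|` swaps are attempted.
#'
#' @param net `fn_network` with at least 2 edges.
#' @param seed seed; output is a deterministic function of `(net, seed)`.
#' @return rewired `fn_network`; the number of accepted swaps is recorded
#'   in `provenance$swaps`.
#' @export
rewire_null <- function(net, seed = 1) {
  stopifnot(inherits(net, "fn_network"))
  w <- net$weights
  n <- nrow(w)
  p <- upper_pairs(n)
  onedge <- w[cbind(p[, 1], p[, 2])] != 0
  edges <- p[onedge, , drop = FALSE]
  wts <- w[edges]
  m <- nrow(edges)
  if (m < 2) stopf("rewiring needs at least 2 edges")
  adj <- net$adjacency > 0
  accepted <- 0L
  with_seed(seed, {
    attempts <- 10L * m
    e1s <- sample.int(m, attempts, replace = TRUE)
    e2s <- sample.int(m, attempts, replace = TRUE)
    flips <- stats::runif(attempts) < 0.5
    for (t in seq_len(attempts)) {
      i1 <- e1s[t]; i2 <- e2s[t]
      if (i1 == i2) next
      a <- edges[i1, 1]; b <- edges[i1, 2]
      c <- edges[i2, 1]; d <- edges[i2, 2]
      if (flips[t]) { tmp <- c; c <- d; d <- tmp }
      # propose (a,d) and (c,b)
      if (a == d || c == b) next
      if (length(unique(c(a, b, c, d))) < 4) next
      if (adj[a, d] || adj[c, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c, d] <- adj[d, c] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[c, b] <- adj[b, c] <- TRUE
      edges[i1, ] <- c(min(a, d), max(a, d))
      edges[i2, ] <- c(min(c, b), max(c, b))
      accepted <- accepted + 1L
    }
  })
  w2 <- matrix(0, n, n, dimnames = dimnames(w))
  w2[edges] <- wts
  w2[edges[, c(2, 1), drop = FALSE]] <- wts
  weighted_network(w2, provenance = c(net$provenance,
                                      list(rewired = TRUE, swaps = accepted,
                                           rewire_seed = seed)))
}

#' @export
print.fn_global_metrics <- function(x, ...) {
  cat("Global network metrics\n")
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
  cat(sprintf("  strength (%s)    %s\n", x$strength_summary,
              fmt(x$network_strength)))
  cat(sprintf("  clustering Cp    %s\n", fmt(x$clustering_coefficient)))
  cat(sprintf("  path length Lp   %s (%d unreachable pairs)\n",
              fmt(x$shortest_path_length), x$unreachable_pairs))
  cat(sprintf("  small-world      sigma %s (gamma %s / lambda %s, %d nulls)\n",
              fmt(x$small_worldness), fmt(x$gamma), fmt(x$lambda),
              x$null_model_summary$n_null))
  cat(sprintf("  efficiency       global %s, local %s\n",
              fmt(x$global_efficiency), fmt(x$local_efficiency)))
  cat(sprintf("  hierarchy        %s (excluded %d nodes)\n",
              fmt(x$hierarchy), x$hierarchy_excluded_nodes))
  cat(sprintf("  assortativity    %s\n", fmt(x$assortativity)))
  invisible(x)
}

#' Collect global metrics into a one-row data frame
#' @param x `fn_global_metrics`.
#' @param ... unused.
#' @return data frame with one numeric column per metric.
#' @export
as.data.frame.fn_global_metrics <- function(x, ...) {
  data.frame(network_strength = x$network_strength,
             clustering_coefficient = x$clustering_coefficient,
             shortest_path_length = x$shortest_path_length,
             small_worldness = x$small_worldness,
             global_efficiency = x$global_efficiency,
             local_efficiency = x$local_efficiency,
             hierarchy = x$hierarchy,
             assortativity = x$assortativity)
}
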
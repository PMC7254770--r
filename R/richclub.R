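#' Weighted rich-club curve with null-model normalization
#'
#' For each degree level k, the club is the set of nodes with binary degree
#' greater than k. The weighted rich-club coefficient is the total weight
#' of edges inside the club divided by the sum of the same number of
#' strongest weights anywhere in the network. The normalized curve divides
#' by the mean coefficient of degree-and-weight preserving rewired nulls;
#' values above 1 over a range of k indicate rich-club organization.
#' Levels where fewer than 2 nodes exceed k, or where the club has no
#' edges, are stored as missing rather than 0.
#'
#' @param net `fn_network` with nonnegative weights.
#' @param n_null number of rewired nulls (default 100).
#' @param seed seed for the null ensemble.
#' @param null_networks optional explicit null ensemble (list of
#'   `fn_network`); overrides `n_null`/`seed`.
#' @return object of class `fn_richclub`: data frame columns `k`, `phi`,
#'   `phi_rand`, `phi_norm`.
#' @export
rich_club_curve <- function(net, n_null = 100, seed = 1,
                            null_networks = NULL) {
  stopifnot(inherits(net, "fn_network"))
  check_nonnegative(net)
  deg <- rowSums(net$adjacency)
  if (sum(net$adjacency) == 0 || max(deg) < 2) {
    return(structure(data.frame(k = integer(0), phi = numeric(0),
                                phi_rand = numeric(0), phi_norm = numeric(0)),
                     class = c("fn_richclub", "data.frame")))
  }
  ks <- seq_len(max(deg) - 1L)
  phi <- phi_weighted(net$weights, deg, ks)
  if (is.null(null_networks)) {
    null_networks <- lapply(seq_len(n_null), function(r) {
      rewire_null(net, seed = seed + r)
    })
  }
  null_phi <- vapply(null_networks, function(g) {
    phi_weighted(g$weights, rowSums(g$adjacency), ks)
  }, numeric(length(ks)))
  if (length(ks) == 1L) null_phi <- matrix(null_phi, nrow = 1)
  phi_rand <- rowMeans(null_phi, na.rm = TRUE)
  phi_rand[!is.finite(phi_rand)] <- NA
  structure(data.frame(k = ks, phi = phi, phi_rand = phi_rand,
                       phi_norm = phi / phi_rand),
            class = c("fn_richclub", "data.frame"))
}

# weighted rich-club coefficient at each k (vector over ks)
phi_weighted <- function(w, deg, ks) {
  ranked <- sort(w[upper.tri(w)][w[upper.tri(w)] != 0], decreasing = TRUE)
  vapply(ks, function(k) {
    club <- which(deg > k)
    if (length(club) < 2) return(NA_real_)
    sub <- w[club, club, drop = FALSE]
    e_club <- sum(sub[upper.tri(sub)] != 0)
    if (e_club == 0) return(NA_real_)
    sum(sub[upper.tri(sub)]) / sum(ranked[seq_len(e_club)])
  }, numeric(1))
}

#' Identify hub regions from a group of networks
#'
#' Ranks regions by their mean nodal degree (binary by default, strength
#' optionally) across all supplied networks — both groups pooled — and
#' selects the top `ceiling(fraction * N)` regions. Ties at the selection
#' boundary are all included and the inflation recorded.
#'
#' @param networks list of `fn_network` sharing one region ordering.
#' @param fraction fraction of regions to select (default 0.15; 0.15 of 90
#'   regions gives 14 hubs, 0.10 gives 9, 0.20 gives 18).
#' @param ranking `"degree"` (default) or `"strength"`.
#' @return character vector of hub labels with attributes `mean_rank_value`
#'   (named vector over all regions) and `tie_inflation` (number of extra
#'   regions included by boundary ties).
#' @export
identify_hubs <- function(networks, fraction = 0.15,
                          ranking = c("degree", "strength")) {
  ranking <- match.arg(ranking)
  if (!(fraction > 0 && fraction < 1)) stopf("fraction must lie in (0, 1)")
  if (inherits(networks, "fn_network")) networks <- list(networks)
  labels <- networks[[1]]$region_labels
  for (g in networks) {
    if (!identical(g$region_labels, labels)) {
      stopf("all networks must share the same region ordering")
    }
  }
  vals <- vapply(networks, function(g) {
    if (ranking == "degree") rowSums(g$adjacency) else rowSums(g$weights)
  }, numeric(length(labels)))
  if (length(labels) == 1L) vals <- matrix(vals, nrow = 1)
  mv <- rowMeans(vals)
  names(mv) <- labels
  n_hub <- as.integer(ceiling(fraction * length(labels)))
  ord <- order(mv, decreasing = TRUE)
  cutoff <- mv[ord[n_hub]]
  sel <- mv >= cutoff
  hubs <- labels[sel]
  structure(hubs,
            mean_rank_value = mv,
            tie_inflation = as.integer(sum(sel) - n_hub))
}

#' Classify edges as rich-club, feeder or local connections
#'
#' Edges with both endpoints in the hub set are rich-club connections,
#' edges with exactly one endpoint are feeders, and edges between non-hub
#' nodes are local connections. Per class, the summary reports strength
#' (sum of weights), degree (edge count) and average strength
#' (strength / degree, missing for empty classes).
#'
#' @param net `fn_network`.
#' @param hub_set character vector of hub labels (subset of the regions).
#' @return object of class `fn_edge_classes`: list with `edges` (data frame
#'   `region_i`, `region_j`, `weight`, `class`) and `summary` (data frame
#'   `class`, `strength`, `degree`, `average_strength`).
#' @export
classify_connections <- function(net, hub_set) {
  stopifnot(inherits(net, "fn_network"))
  if (!all(hub_set %in% net$region_labels)) {
    stopf("hub_set contains regions not in the network")
  }
  ed <- network_edges(net)
  in_i <- ed$region_i %in% hub_set
  in_j <- ed$region_j %in% hub_set
  ed$class <- ifelse(in_i & in_j, "rich_club",
                     ifelse(in_i | in_j, "feeder", "local"))
  classes <- c("rich_club", "feeder", "local")
  summ <- do.call(rbind, lapply(classes, function(cl) {
    sel <- ed$class == cl
    k <- sum(sel)
    s <- sum(ed$weight[sel])
    data.frame(class = cl, strength = s, degree = k,
               average_strength = if (k > 0) s / k else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(edges = ed, summary = summ, hub_set = hub_set),
            class = "fn_edge_classes")
}

#' @export
print.fn_richclub <- function(x, ...) {
  def <- sum(is.finite(x$phi))
  cat(sprintf("Rich-club profile: %d degree levels (%d defined)\n",
              nrow(x), def))
  if (def > 0) {
    kk <- x$k[is.finite(x$phi_norm)]
    if (length(kk)) {
      cat(sprintf("  phi_norm range [%.3f, %.3f] over k in [%d, %d]\n",
                  min(x$phi_norm, na.rm = TRUE), max(x$phi_norm, na.rm = TRUE),
                  min(kk), max(kk)))
    }
  }
  invisible(x)
}

#' @export
print.fn_edge_classes <- function(x, ...) {
  cat(sprintf("Connection classes (%d hubs):\n", length(x$hub_set)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
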
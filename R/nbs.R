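#' Network-based statistic (NBS) for two-group edgewise comparison
#'
#' Edgewise two-sample t-tests on connection weights (absent edges
#' contribute weight 0), a primary uncorrected threshold to define
#' suprathreshold connections, connected components of the suprathreshold
#' graph, and a permutation null of the maximal component size (in links)
#' to assign each observed component a family-wise-error corrected p-value:
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' By default both one-sided families (`A > B` and `B > A`) are analysed
#' separately at the primary threshold, matching directional reporting of
#' hyper-/hypo-connected subnetworks; a two-sided mode is available. Each
#' one-sided family has its own permutation null and controls its own
#' family-wise error.
#'
#' @param group_a,group_b lists of `fn_network` sharing one region order.
#' @param primary_alpha primary uncorrected threshold (default 0.001).
#' @param n_permutations number of label permutations (default 5000).
#' @param seed permutation seed.
#' @param direction `"both"` (default), `"A>B"`, `"B>A"` or `"two.sided"`.
#' @param edge_presence_fraction edges are tested only when nonzero in at
#'   least this fraction of all subjects (default 0: present in >= 1
#'   subject).
#' @param var_equal pooled (default) vs Welch variance for the edge tests.
#' @return object of class `fn_nbs`: list with `t_matrix`, `df`,
#'   `primary_alpha`, `n_permutations`, `seed`, and per analysed direction
#'   a list holding `suprathreshold_edges`, `components` (each with
#'   `node_set`, `edges`, `size_in_links`, `corrected_p`) and
#'   `null_max_sizes`.
#' @export
nbs <- function(group_a, group_b, primary_alpha = 0.001,
                n_permutations = 5000, seed = 1,
                direction = c("both", "A>B", "B>A", "two.sided"),
                edge_presence_fraction = 0, var_equal = TRUE) {
  direction <- match.arg(direction)
  if (!(primary_alpha > 0 && primary_alpha < 1)) {
    stopf("primary_alpha must lie in (0, 1)")
  }
  if (!is_count(n_permutations) || n_permutations < 1) {
    stopf("n_permutations must be a positive integer")
  }
  labels <- group_a[[1]]$region_labels
  for (g in c(group_a, group_b)) {
    if (!identical(g$region_labels, labels)) {
      stopf("all networks must share the same region ordering")
    }
  }
  n <- length(labels)
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stopf("need at least 2 subjects per group")
  pairs <- upper_pairs(n)
  z <- t(vapply(c(group_a, group_b), function(g) {
    g$weights[pairs]
  }, numeric(nrow(pairs))))
  nsub <- na + nb
  present <- colSums(z != 0)
  min_present <- max(1, ceiling(edge_presence_fraction * nsub))
  mask <- present >= min_present
  zm <- z[, mask, drop = FALSE]
  pm <- pairs[mask, , drop = FALSE]
  df <- nsub - 2

  tvec <- function(ia) {
    xa <- zm[ia, , drop = FALSE]
    xb <- zm[-ia, , drop = FALSE]
    ma <- colMeans(xa); mb <- colMeans(xb)
    va <- colSums(xa^2) - na * ma^2
    vb <- colSums(xb^2) - nb * mb^2
    if (var_equal) {
      sp2 <- (va + vb) / df
      se <- sqrt(sp2 * (1 / na + 1 / nb))
    } else {
      se <- sqrt(va / (na - 1) / na + vb / (nb - 1) / nb)
    }
    d <- ma - mb
    tt <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
    tt
  }
  t_obs <- tvec(seq_len(na))

  dirs <- switch(direction,
    "both" = c("A>B", "B>A"),
    "two.sided" = "two.sided",
    direction
  )
  crit <- if (identical(dirs, "two.sided")) {
    stats::qt(1 - primary_alpha / 2, df)
  } else {
    stats::qt(1 - primary_alpha, df)
  }
  supra_idx <- function(tt, dr) {
    switch(dr,
      "A>B" = which(tt > crit),
      "B>A" = which(tt < -crit),
      "two.sided" = which(abs(tt) > crit)
    )
  }

  # observed components per direction
  observed <- lapply(dirs, function(dr) {
    idx <- supra_idx(t_obs, dr)
    ed <- pm[idx, , drop = FALSE]
    comps <- list()
    if (nrow(ed) > 0) {
      g <- igraph::graph_from_edgelist(
        matrix(as.character(ed), ncol = 2), directed = FALSE)
      memb <- igraph::components(g)$membership
      node_names <- names(memb)
      edge_comp <- memb[as.character(ed[, 1])]
      for (cid in sort(unique(memb))) {
        esel <- which(edge_comp == cid)
        nodes <- as.integer(node_names[memb == cid])
        comps[[length(comps) + 1]] <- list(
          node_set = labels[sort(nodes)],
          edges = data.frame(
            region_i = labels[ed[esel, 1]],
            region_j = labels[ed[esel, 2]],
            t = t_obs[idx[esel]],
            stringsAsFactors = FALSE),
          edge_index = cbind(ed[esel, 1], ed[esel, 2]),
          size_in_links = length(esel)
        )
      }
      comps <- comps[order(vapply(comps, `[[`, integer(1), "size_in_links"),
                           decreasing = TRUE)]
    }
    list(direction = dr, suprathreshold_edges = ed, components = comps)
  })
  names(observed) <- dirs

  # permutation null of maximal component size (per direction)
  null_max <- matrix(0L, n_permutations, length(dirs),
                     dimnames = list(NULL, dirs))
  with_seed(seed, {
    for (k in seq_len(n_permutations)) {
      ia <- sample.int(nsub, na)
      tp <- tvec(ia)
      for (j in seq_along(dirs)) {
        idx <- supra_idx(tp, dirs[j])
        null_max[k, j] <- max_component_links(pm[idx, , drop = FALSE])
      }
    }
  })

  for (dr in dirs) {
    nm <- null_max[, dr]
    observed[[dr]]$null_max_sizes <- nm
    observed[[dr]]$components <- lapply(observed[[dr]]$components, function(cp) {
      cp$corrected_p <- (1 + sum(nm >= cp$size_in_links)) / (1 + n_permutations)
      cp
    })
  }

  t_matrix <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  t_matrix[pm] <- t_obs
  t_matrix[pm[, c(2, 1), drop = FALSE]] <- t_obs
  diag(t_matrix) <- 0

  structure(list(t_matrix = t_matrix, df = df,
                 primary_alpha = primary_alpha, t_critical = crit,
                 n_permutations = as.integer(n_permutations), seed = seed,
                 edge_presence_fraction = edge_presence_fraction,
                 n_edges_tested = sum(mask),
                 directions = observed),
            class = "fn_nbs")
}

#' Significant NBS components at a corrected level
#'
#' @param x `fn_nbs`.
#' @param level corrected significance level (default 0.05).
#' @return list of components (each with `direction`, `node_set`, `edges`,
#'   `size_in_links`, `corrected_p`).
#' @export
nbs_significant <- function(x, level = 0.05) {
  stopifnot(inherits(x, "fn_nbs"))
  out <- list()
  for (dr in names(x$directions)) {
    for (cp in x$directions[[dr]]$components) {
      if (cp$corrected_p < level) {
        cp$direction <- dr
        out[[length(out) + 1]] <- cp
      }
    }
  }
  out
}

#' @export
print.fn_nbs <- function(x, ...) {
  cat(sprintf("Network-based statistic: %d edges tested, primary p < %g (|t| > %.3f, df %d), %d permutations\n",
              x$n_edges_tested, x$primary_alpha, x$t_critical, x$df,
              x$n_permutations))
  for (dr in names(x$directions)) {
    comps <- x$directions[[dr]]$components
    if (!length(comps)) {
      cat(sprintf("  %s: no suprathreshold components\n", dr))
    } else {
      for (cp in comps) {
        cat(sprintf("  %s: component with %d nodes, %d links, corrected p = %.4f\n",
                    dr, length(cp$node_set), cp$size_in_links, cp$corrected_p))
      }
    }
  }
  invisible(x)
}
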
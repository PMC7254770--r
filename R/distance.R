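#' Equal-range distance terciles from extreme centroid distances
#'
#' Divides the interval from the shortest to the longest possible
#' inter-node distance into three equal ranges; e.g. extremes of 7.61 mm
#' and 150.98 mm give boundaries 55.40 mm and 103.19 mm.
#'
#' @param d_min,d_max shortest and longest pairwise centroid distance (mm).
#' @return numeric vector `c(b1, b2)` of the two interior boundaries.
#' @export
tercile_boundaries <- function(d_min, d_max) {
  if (!(d_max > d_min) || d_min < 0) stopf("need 0 <= d_min < d_max")
  step <- (d_max - d_min) / 3
  c(b1 = d_min + step, b2 = d_min + 2 * step)
}

#' Distance stratification bins for an atlas
#'
#' Computes all pairwise Euclidean centroid distances, finds their extremes
#' and splits the range into three equal-width bins: short
#' `[d_min, b1]`, medium `(b1, b2]`, long `(b2, d_max]`.
#'
#' @param atlas `fn_atlas` with at least 2 regions.
#' @return object of class `fn_distance_bins`: list with `d_min`, `d_max`,
#'   `boundaries` (b1, b2) and the full `distance` matrix (mm).
#' @export
distance_bins <- function(atlas) {
  stopifnot(inherits(atlas, "fn_atlas"))
  if (atlas$n_regions < 2) stopf("need at least 2 regions")
  d <- centroid_distances(atlas)
  up <- d[upper.tri(d)]
  b <- tercile_boundaries(min(up), max(up))
  structure(list(d_min = min(up), d_max = max(up), boundaries = b,
                 distance = d),
            class = "fn_distance_bins")
}

#' Assign edges to short/medium/long distance bins
#'
#' @param edges data frame with columns `region_i`, `region_j` (atlas
#'   labels); e.g. the output of [network_edges()] or the edge table of an
#'   NBS component.
#' @param bins `fn_distance_bins` computed from the same atlas.
#' @return object of class `fn_edge_distances`: the edge table with added
#'   `distance_mm` and `distance_bin` columns, plus `proportions` (named
#'   short/medium/long fractions over the supplied edge set).
#' @export
stratify_edges <- function(edges, bins) {
  stopifnot(inherits(bins, "fn_distance_bins"))
  edges <- as.data.frame(edges)
  labels <- rownames(bins$distance)
  unknown <- setdiff(unique(c(edges$region_i, edges$region_j)), labels)
  if (length(unknown)) {
    stopf("edge references unknown region(s): %s",
          paste(unknown, collapse = ", "))
  }
  dmm <- bins$distance[cbind(match(edges$region_i, labels),
                             match(edges$region_j, labels))]
  b <- bins$boundaries
  bin <- ifelse(dmm <= b[1], "short", ifelse(dmm <= b[2], "medium", "long"))
  edges$distance_mm <- dmm
  edges$distance_bin <- factor(bin, levels = c("short", "medium", "long"))
  prop <- prop.table(table(edges$distance_bin))
  structure(list(edges = edges,
                 proportions = stats::setNames(as.numeric(prop), names(prop)),
                 boundaries = b),
            class = "fn_edge_distances")
}

#' @export
print.fn_distance_bins <- function(x, ...) {
  cat(sprintf("Distance terciles: short [%.2f, %.2f], medium (%.2f, %.2f], long (%.2f, %.2f] mm\n",
              x$d_min, x$boundaries[1], x$boundaries[1], x$boundaries[2],
              x$boundaries[2], x$d_max))
  invisible(x)
}

#' @export
print.fn_edge_distances <- function(x, ...) {
  cat(sprintf("Edge distance stratification (%d edges):\n", nrow(x$edges)))
  cat(sprintf("  short %.1f%%, medium %.1f%%, long %.1f%%\n",
              100 * x$proportions["short"], 100 * x$proportions["medium"],
              100 * x$proportions["long"]))
  invisible(x)
}
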
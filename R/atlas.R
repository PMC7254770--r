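#' Atlas definitions: region labels and centroid coordinates
#'
#' An atlas is the node set of every network in the package: an ordered list
#' of region labels plus one stereotactic centroid (x, y, z, in mm) per
#' region. Edge lengths in physical space (connection distance) are
#' Euclidean distances between centroids.
#'
#' @param labels character vector of unique region labels.
#' @param centroids numeric matrix (n x 3) of centroid coordinates in mm.
#' @return An object of class `fn_atlas`: list with `labels`, `centroids`
#'   (rownames = labels) and `n_regions`.
#' @export
atlas_definition <- function(labels, centroids) {
  labels <- as.character(labels)
  centroids <- as.matrix(centroids)
  if (anyDuplicated(labels)) stopf("atlas labels must be unique")
  if (nrow(centroids) != length(labels) || ncol(centroids) != 3) {
    stopf("centroids must be a %d x 3 matrix", length(labels))
  }
  if (!all(is.finite(centroids))) stopf("centroid coordinates must be finite")
  d <- as.matrix(stats::dist(centroids))
  diag(d) <- NA
  if (any(d == 0, na.rm = TRUE)) {
    stopf("coincident centroids: two distinct regions at the same coordinates")
  }
  rownames(centroids) <- labels
  colnames(centroids) <- c("x", "y", "z")
  structure(
    list(labels = labels, centroids = centroids, n_regions = length(labels)),
    class = "fn_atlas"
  )
}

#' Bundled 90-region atlas with synthetic centroid coordinates
#'
#' Returns the package's default 90-region atlas. Region labels follow the
#' standard AAL-90 abbreviation scheme (45 left/right pairs, e.g. `PHG.L`,
#' `PCUN.R`); the centroid coordinates are *synthetic* stand-ins with
#' realistic left/right mirror symmetry and spacing, not the coordinates of
#' any published atlas. Any user-supplied atlas of any size can replace it
#' in every downstream operation.
#'
#' @return `fn_atlas` with 90 regions. The minimum and maximum pairwise
#'   centroid distances of the bundled table are attached as attributes
#'   `d_min` / `d_max` and shown by `print`.
#' @export
make_default_atlas <- function() {
  path <- system.file("extdata", "synthetic_aal90_centroids.tsv",
                      package = "funcnet", mustWork = TRUE)
  read_atlas(path)
}

#' Read an atlas from a tab-separated table
#'
#' Expects columns `label`, `x`, `y`, `z`.
#' @param path file path.
#' @return `fn_atlas`.
#' @export
read_atlas <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stopf("atlas table %s must have columns label, x, y, z", path)
  }
  at <- atlas_definition(tab$label, as.matrix(tab[, c("x", "y", "z")]))
  d <- centroid_distances(at)
  attr(at, "d_min") <- min(d[upper.tri(d)])
  attr(at, "d_max") <- max(d[upper.tri(d)])
  at
}

#' Write an atlas to a tab-separated table
#' @param atlas `fn_atlas`.
#' @param path file path.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "fn_atlas"))
  tab <- data.frame(label = atlas$labels,
                    x = atlas$centroids[, 1],
                    y = atlas$centroids[, 2],
                    z = atlas$centroids[, 3])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise Euclidean centroid distances (mm)
#' @param atlas `fn_atlas`.
#' @return symmetric n x n matrix of distances, zero diagonal.
#' @export
centroid_distances <- function(atlas) {
  stopifnot(inherits(atlas, "fn_atlas"))
  d <- as.matrix(stats::dist(atlas$centroids))
  dimnames(d) <- list(atlas$labels, atlas$labels)
  d
}

#' @export
print.fn_atlas <- function(x, ...) {
  cat(sprintf("Atlas: %d regions\n", x$n_regions))
  d <- centroid_distances(x)
  up <- d[upper.tri(d)]
  cat(sprintf("  pairwise centroid distance: min %.2f mm, max %.2f mm\n",
              min(up), max(up)))
  cat("  labels:", paste(utils::head(x$labels, 6), collapse = ", "),
      if (x$n_regions > 6) "..." else "", "\n")
  invisible(x)
}
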
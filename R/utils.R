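# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= 0
}

#' @noRd
check_symmetric <- function(m, name = "matrix", tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stopf("%s must be a square matrix", name)
  }
  if (max(abs(m - t(m)), na.rm = TRUE) > tol) {
    stopf("%s must be symmetric", name)
  }
  invisible(TRUE)
}

#' Upper-triangle pair index table in row-major order
#'
#' Pairs (i, j), i < j, ordered by i then j: (1,2), (1,3), ..., (2,3), ...
#' This fixed order defines edge vectorization throughout the package.
#' @noRd
upper_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Row-major pair order (1,2), (1,3), ..., (2,3), ...; the inverse of
#' [unvec_upper()].
#' @param m symmetric numeric matrix.
#' @return numeric vector of length `n(n-1)/2`, named `"Ri--Rj"` when `m`
#'   has dimnames.
#' @export
vec_upper <- function(m) {
  check_symmetric(m, "m")
  p <- upper_pairs(nrow(m))
  v <- m[cbind(p[, 1], p[, 2])]
  if (!is.null(rownames(m))) {
    names(v) <- paste0(rownames(m)[p[, 1]], "--", rownames(m)[p[, 2]])
  }
  v
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' @param v vector produced by [vec_upper()].
#' @param labels optional region labels (length n).
#' @param diag value placed on the diagonal (default 0).
#' @return symmetric n x n matrix.
#' @export
unvec_upper <- function(v, labels = NULL, diag = 0) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-8) stopf("length %d is not n(n-1)/2", length(v))
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  p <- upper_pairs(n)
  m[cbind(p[, 1], p[, 2])] <- v
  m <- m + t(m)
  diag(m) <- diag
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Maximal connected-component size (in links) of an edge list
#'
#' Union-find over the endpoints of `edges` (2-column integer matrix);
#' returns the largest number of edges in one connected component.
#' @noRd
max_component_links <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(0L)
  nodes <- sort(unique(as.vector(edges)))
  idx <- match(edges, nodes)
  dim(idx) <- dim(edges)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_len(nrow(idx))) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  edge_root <- roots[idx[, 1]]
  max(tabulate(edge_root, nbins = length(nodes)))
}
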
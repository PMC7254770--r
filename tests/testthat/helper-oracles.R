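# Fixture generators and independent brute-force oracles used across tests.
# Oracles deliberately use naive enumeration, not the package's code paths.

rand_weighted_net <- function(n, p = 0.4, seed = 1, wmin = 0.1, wmax = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[runif(length(up)) < p]
  w[on] <- runif(length(on), wmin, wmax)
  w <- w + t(w)
  weighted_network(w)
}

# all-pairs shortest paths on lengths 1/w by exhaustive relaxation
# (Floyd-Warshall)
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# geometric-mean triangle clustering by explicit triple enumeration
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  ww <- w / mx
  vapply(seq_len(n), function(i) {
    k <- sum(w[i, ] > 0)
    if (k < 2) return(0)
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h && w[i, j] > 0 && w[i, h] > 0 &&
            w[j, h] > 0) {
          acc <- acc + (ww[i, j] * ww[i, h] * ww[j, h])^(1 / 3)
        }
      }
    }
    acc / (k * (k - 1))
  }, numeric(1))
}

oracle_nodal <- function(w) {
  n <- nrow(w)
  d <- oracle_distances(w)
  eg <- vapply(seq_len(n), function(i) {
    x <- 1 / d[i, -i]
    mean(ifelse(is.finite(x), x, 0))
  }, numeric(1))
  l <- vapply(seq_len(n), function(i) {
    x <- d[i, -i]
    x <- x[is.finite(x)]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  el <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- w[nb, nb, drop = FALSE]
    ds <- oracle_distances(sub)
    m <- length(nb)
    acc <- 0
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (a != b && is.finite(ds[a, b])) acc <- acc + 1 / ds[a, b]
    }
    acc / (m * (m - 1))
  }, numeric(1))
  list(strength = unname(rowSums(w)), degree = unname(rowSums(w > 0)),
       clustering = oracle_clustering(w), shortest_path_length = l,
       global_efficiency = eg, local_efficiency = el)
}

# weighted rich-club coefficient at level k by direct enumeration
oracle_phi <- function(w, k) {
  deg <- rowSums(w > 0)
  club <- which(deg > k)
  if (length(club) < 2) return(NA_real_)
  wts <- sort(w[upper.tri(w)][w[upper.tri(w)] > 0], decreasing = TRUE)
  s <- 0; e <- 0
  for (a in club) for (b in club) {
    if (a < b && w[a, b] > 0) { s <- s + w[a, b]; e <- e + 1 }
  }
  if (e == 0) return(NA_real_)
  s / sum(wts[seq_len(e)])
}

# pooled-variance two-sample t from the textbook sums
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), na + nb - 2)
  list(t = t, p = p)
}

# AUC as the rank (concordance) statistic with ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- which(labels == "B"); neg <- which(labels == "A")
  acc <- 0
  for (i in pos) for (j in neg) {
    acc <- acc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  acc / (length(pos) * length(neg))
}

# quick toy atlas
toy_atlas <- function() {
  atlas_definition(c("X", "Y", "Z"),
                   rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 10)))
}

# small group of subject networks drawn around a base weight matrix
sim_group_nets <- function(n_sub, base, noise = 0.05, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_sub), function(s) {
    nn <- nrow(base)
    e <- matrix(0, nn, nn)
    e[upper.tri(e)] <- rnorm(sum(upper.tri(e)), 0, noise)
    w <- pmax(base + e + t(e), 0)
    diag(w) <- 0
    weighted_network(w)
  })
}

# cohort of subject networks whose first 10 pairs carry a group effect
classif_fixture <- function(n_per = 10, shift = 0.5, n_reg = 10, seed = 2,
                            noise = 0.08) {
  set.seed(seed)
  mknet <- function(s) {
    w <- matrix(0, n_reg, n_reg)
    p <- which(upper.tri(w))
    v <- pmax(0, 0.3 + rnorm(length(p), 0, noise))
    v[1:10] <- v[1:10] + s
    w[p] <- v
    w <- w + t(w)
    weighted_network(w)
  }
  nets <- c(replicate(n_per, mknet(0), simplify = FALSE),
            replicate(n_per, mknet(shift), simplify = FALSE))
  nodal <- lapply(nets, nodal_metrics)
  build_features(nets, nodal, rep(c("A", "B"), each = n_per))
}

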
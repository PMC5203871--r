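# Independent oracles used across the suite. They deliberately avoid the
# code paths they check: shortest-path quantities come from adjacency-matrix
# powers and Floyd-Warshall, hypergeometric tails from explicit binomial
# coefficients.

# distance matrix by Floyd-Warshall on a 0/1 adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
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

# shortest-path counts: sigma[s,t] = number of geodesics = walks of length
# d(s,t), read off the d-th power of the adjacency matrix
oracle_path_counts <- function(adj, dist) {
  n <- nrow(adj)
  pows <- vector("list", max(1L, n - 1L))
  pows[[1L]] <- adj
  for (k in seq_len(n - 2L)) pows[[k + 1L]] <- pows[[k]] %*% adj
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s != t && is.finite(dist[s, t])) {
        sigma[s, t] <- pows[[dist[s, t]]][s, t]
      }
    }
  }
  sigma
}

# pair-normalized betweenness by direct summation over pairs
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  if (n < 3L) return(numeric(n))
  dist <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, dist)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        if (s == v || t == v || !is.finite(dist[s, t])) next
        if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# component-scaled closeness from the Floyd-Warshall distances
oracle_closeness <- function(adj) {
  n <- nrow(adj)
  dist <- oracle_distances(adj)
  vapply(seq_len(n), function(v) {
    reach <- which(is.finite(dist[v, ]))
    nv <- length(reach)  # component size incl. v
    if (nv < 2L) return(0)
    ((nv - 1) / (n - 1)) * ((nv - 1) / sum(dist[v, reach]))
  }, numeric(1))
}

# upper-tail hypergeometric by explicit enumeration over overlap sizes
oracle_hyper_tail <- function(k, N, K, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# random labelled graph on n nodes, edge probability p, as adjacency matrix
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(stats::runif(length(up)) < p)
  adj + t(adj)
}

# wrap an adjacency matrix as a typed network with generic protein roles
tn_from_adj <- function(adj) {
  n <- nrow(adj)
  nodes <- sprintf("N%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- if (nrow(idx)) data.frame(a = nodes[idx[, 1L]], b = nodes[idx[, 2L]])
  typed_network(nodes, rep("other_protein", n), edges)
}

# study-scale bundle, generated once per test run
study_bundle_env <- new.env(parent = emptyenv())
study_bundle <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(study_bundle_env[[key]])) {
    dir <- file.path(tempdir(), paste0("netpharm-bundle-", seed))
    paths <- generate_study_bundle(seed, dir)
    herbs <- read_herb_compound_table(paths$herbs)
    ct <- read_compound_target_table(paths$compound_targets, herbs = herbs)
    study_bundle_env[[key]] <- list(
      paths = paths, herbs = herbs, ct = ct,
      disease = read_disease_targets(paths$disease_targets),
      ppi = suppressMessages(read_scored_interactions(paths$ppi, 0.4)),
      anns = read_gmt(paths$annotations),
      pharm = read_pharm_efficacy_table(paths$pharm_efficacy)
    )
  }
  study_bundle_env[[key]]
}
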
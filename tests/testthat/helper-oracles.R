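# Independent brute-force oracles used to check the graph and signal code.

# All-pairs shortest paths by Floyd-Warshall on an edge-length matrix
# (Inf = no edge). Independent of the igraph-based implementation.
fw_distances <- function(len) {
  n <- nrow(len)
  D <- len
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_path_length <- function(W) {
  len <- ifelse(W > 0, 1 / W, Inf)
  D <- fw_distances(len)
  off <- row(D) != col(D)
  mean(D[off & is.finite(D)])
}

oracle_efficiency <- function(W) {
  len <- ifelse(W > 0, 1 / W, Inf)
  D <- fw_distances(len)
  off <- row(D) != col(D)
  mean(ifelse(is.finite(D[off]), 1 / D[off], 0))
}

# Binary clustering coefficient by explicit neighbor-pair enumeration.
oracle_clustering <- function(A) {
  n <- nrow(A)
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (u in nb) for (v in nb) if (u != v && A[u, v] > 0) e <- e + 1
    Ci[i] <- e / (k * (k - 1))
  }
  mean(Ci)
}

# Random symmetric weighted graph with the given edge probability.
random_weighted_graph <- function(n, p = 0.5) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < p
  W[ut[on]] <- runif(sum(on), 0.1, 1)
  W + t(W)
}

# Exhaustive windowed argmax used to cross-check the P50 detector.
oracle_peak <- function(trace, times_ms, lo, hi) {
  best <- -Inf; best_t <- NA
  for (s in seq_along(trace)) {
    if (times_ms[s] >= lo && times_ms[s] <= hi && trace[s] > best) {
      best <- trace[s]; best_t <- times_ms[s]
    }
  }
  list(amplitude = best, latency = best_t)
}

# Plug-in entropy via base-R table() on pre-cut factors - a separate code
# path from the package's tabulate-based estimator.
oracle_joint_entropy <- function(ix, iy) {
  p <- as.vector(table(ix, iy))
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

# Small helper: a tiny cohort configuration that keeps unit tests fast.
tiny_config <- function(..., seed = 11L) {
  synth_config(n_per_group = c(FESZ = 3L, UHR = 3L, HC = 3L),
               n_trials = 12L, n_sensors = 16L, seed = seed, ...)
}
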
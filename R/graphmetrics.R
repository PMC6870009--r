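# Weighted shortest-path distance matrix with edge length 1/weight
# (absent edge = no link). Uses igraph's Dijkstra under the hood.
shortest_path_lengths <- function(W) {
  W <- conn_values(W)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-8) stop("matrix must be symmetric")
  if (any(W < 0)) stop("weights must be nonnegative")
  diag(W) <- 0
  L <- ifelse(W > 0, 1 / W, 0)
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, weights = igraph::E(g)$weight)
}

#' Characteristic path length of a weighted network
#'
#' Mean weighted shortest-path length over all ordered node pairs, with
#' edge lengths 1/weight. Disconnected pairs are excluded from the mean
#' (with a warning); a network with no finite path at all is an error.
#'
#' @param W symmetric nonnegative weight matrix (or
#'   `connectivity_matrix`).
#' @return characteristic path length L.
#' @export
characteristic_path_length <- function(W) {
  D <- shortest_path_lengths(W)
  off <- row(D) != col(D)
  finite <- off & is.finite(D)
  if (!any(finite)) stop("network is fully disconnected")
  if (any(off & !is.finite(D)))
    warning("disconnected node pairs excluded from the path-length mean")
  mean(D[finite])
}

#' Global efficiency of a weighted network
#'
#' Mean over ordered node pairs of the reciprocal weighted shortest-path
#' length; disconnected pairs contribute 0.
#'
#' @inheritParams characteristic_path_length
#' @return global efficiency in `[0, 1]` for weights in `[0, 1]`.
#' @export
global_efficiency <- function(W) {
  D <- shortest_path_lengths(W)
  off <- row(D) != col(D)
  inv <- ifelse(is.finite(D) & D > 0, 1 / D, 0)
  mean(inv[off])
}

#' Binarize a weighted network at a proportional threshold
#'
#' Keeps the strongest `density * n(n-1)/2` edges (ties broken by stable
#' edge index order) and returns the binary adjacency matrix.
#'
#' @inheritParams characteristic_path_length
#' @param density fraction of possible edges kept, in (0, 1].
#' @return binary symmetric adjacency matrix.
#' @export
binarize_proportional <- function(W, density) {
  W <- conn_values(W)
  stopifnot(density > 0, density <= 1)
  n <- nrow(W)
  ut <- which(upper.tri(W))
  w <- W[ut]
  m <- round(density * n * (n - 1) / 2)
  pos <- which(w > 0)
  keep <- pos[order(-w[pos], pos)][seq_len(min(m, length(pos)))]
  A <- matrix(0, n, n)
  A[ut[keep]] <- 1
  A + t(A)
}

#' Average clustering coefficient on a proportionally thresholded graph
#'
#' Binarizes the weighted network at the given density, then computes the
#' binary clustering coefficient of each node,
#' \eqn{C_i = E_i / (k_i (k_i - 1))} with \eqn{E_i} the ordered-pair count
#' of closed triangles at i (\eqn{C_i = 0} for \eqn{k_i < 2}), and averages
#' over nodes.
#'
#' @inheritParams characteristic_path_length
#' @param density proportional threshold (default 0.2); pass 1 to keep all
#'   positive edges (e.g. when `W` is already binary).
#' @return average clustering coefficient in `[0, 1]`.
#' @export
average_clustering <- function(W, density = 0.2) {
  A <- binarize_proportional(W, density)
  k <- rowSums(A)
  Ei <- diag(A %*% A %*% A)                       # ordered triangle pairs
  Ci <- ifelse(k >= 2, Ei / (k * (k - 1)), 0)
  mean(Ci)
}

#' Graph-metric feature vector for one subject
#'
#' Computes clustering coefficient (CLU), characteristic path length (CHA)
#' and global efficiency (EFF) for the S1, S2 and gating (S1-S2) condition
#' networks — the 9 network features of the staging classifier, in the
#' canonical order S1_CLU, S2_CLU, S1_S2_CLU, S1_CHA, S2_CHA, S1_S2_CHA,
#' S1_EFF, S2_EFF, S1_S2_EFF.
#'
#' @param mats named list with elements `S1`, `S2`, `S1_S2` (weight
#'   matrices or `connectivity_matrix` objects).
#' @param density proportional threshold used for the clustering
#'   coefficient (default 0.2); path length and efficiency use the full
#'   weighted graph.
#' @return named numeric vector of length 9.
#' @export
metrics_for_subject <- function(mats, density = 0.2) {
  need <- c("S1", "S2", "S1_S2")
  if (!all(need %in% names(mats)))
    stop("missing condition matrix: ",
         paste(setdiff(need, names(mats)), collapse = ", "))
  clu <- vapply(need, function(cc) average_clustering(mats[[cc]], density),
                numeric(1))
  cha <- vapply(need, function(cc) characteristic_path_length(mats[[cc]]),
                numeric(1))
  eff <- vapply(need, function(cc) global_efficiency(mats[[cc]]),
                numeric(1))
  out <- c(clu, cha, eff)
  names(out) <- c("S1_CLU", "S2_CLU", "S1_S2_CLU",
                  "S1_CHA", "S2_CHA", "S1_S2_CHA",
                  "S1_EFF", "S2_EFF", "S1_S2_EFF")
  out
}
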
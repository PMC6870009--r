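# Stack a list of connectivity matrices into subjects x edges rows
# (upper triangle, column-major edge order shared by all callers).
edge_stack <- function(nets) {
  mats <- lapply(nets, conn_values)
  n <- nrow(mats[[1]])
  if (any(vapply(mats, function(m) nrow(m) != n || ncol(m) != n, logical(1))))
    stop("connectivity matrices must share one atlas")
  ut <- which(upper.tri(mats[[1]]))
  E <- t(vapply(mats, function(m) m[ut], numeric(length(ut))))
  ij <- arrayInd(ut, c(n, n))
  list(E = E, node_i = ij[, 1], node_j = ij[, 2], n_nodes = n)
}

#' Edge-wise permutation test between two groups of networks
#'
#' Per edge, the statistic is the difference of group means of the edge
#' weight. The null is built by shuffling group labels across the pooled
#' subjects and recomputing every edge statistic `n_perm` times; two-sided
#' p-values use the add-one rule \eqn{p = (1 + \#\{|null| \ge |obs|\}) /
#' (1 + n_perm)}. When the total number of group assignments is at most
#' `exact_limit` the null is enumerated exactly instead. No cross-edge
#' correction is applied: an edge is significant when `p < alpha`.
#'
#' @param nets_A,nets_B lists of per-subject connectivity matrices (or
#'   `connectivity_matrix` objects) on the same atlas, >= 2 subjects each.
#' @param n_perm permutation count (default 5000; < 100 draws a warning).
#' @param alpha per-edge significance level (default 0.05).
#' @param seed integer seed for the label shuffles.
#' @param exact_limit enumerate the null exactly when the number of
#'   distinct assignments is at most this (default 20000).
#' @return object of class `edge_test`: `p_values`, `observed_diff`,
#'   `node_i`, `node_j`, `significant` (data.frame of significant edges
#'   with sign), `alpha`, `n_perm`, `exact`, `seed`, `n_nodes`.
#' @export
edge_permutation_test <- function(nets_A, nets_B, n_perm = 5000L,
                                  alpha = 0.05, seed = 1L,
                                  exact_limit = 20000) {
  nA <- length(nets_A); nB <- length(nets_B)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 subjects")
  if (n_perm < 100) warning("fewer than 100 permutations: p-values coarse")
  sa <- edge_stack(nets_A)
  sb <- edge_stack(nets_B)
  if (sa$n_nodes != sb$n_nodes)
    stop("groups are not aligned on the same atlas")
  E <- rbind(sa$E, sb$E)
  n <- nA + nB
  ne <- ncol(E)
  obs <- colMeans(E[seq_len(nA), , drop = FALSE]) -
    colMeans(E[nA + seq_len(nB), , drop = FALSE])

  n_assign <- choose(n, nA)
  exact <- is.finite(n_assign) && n_assign <= exact_limit
  if (exact) {
    sel <- combn(n, nA)
    count <- integer(ne)
    thr <- abs(obs) * (1 - 1e-12) - 1e-15
    for (a in seq_len(ncol(sel))) {
      idx <- sel[, a]
      d <- colMeans(E[idx, , drop = FALSE]) -
        colMeans(E[-idx, , drop = FALSE])
      count <- count + (abs(d) >= thr)
    }
    p <- count / ncol(sel)                     # identity assignment included
    n_used <- ncol(sel)
  } else {
    set.seed(seed)
    thr <- abs(obs) * (1 - 1e-12) - 1e-15
    count <- integer(ne)
    block <- 500L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      Wt <- matrix(-1 / nB, b, n)
      for (r in seq_len(b)) Wt[r, sample.int(n, nA)] <- 1 / nA
      nulls <- Wt %*% E
      count <- count + colSums(abs(nulls) >=
                                 matrix(thr, b, ne, byrow = TRUE))
      done <- done + b
    }
    p <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }

  sig <- which(p < alpha)
  significant <- data.frame(
    node_i = sa$node_i[sig], node_j = sa$node_j[sig],
    observed_diff = obs[sig], p = p[sig],
    sign = ifelse(obs[sig] > 0, "higher", "lower"),
    stringsAsFactors = FALSE
  )
  structure(list(p_values = p, observed_diff = obs,
                 node_i = sa$node_i, node_j = sa$node_j,
                 significant = significant, alpha = alpha,
                 n_perm = n_used, exact = exact, seed = seed,
                 n_nodes = sa$n_nodes,
                 n_subjects = c(A = nA, B = nB)),
            class = "edge_test")
}

#' Node-degree table of significantly different edges
#'
#' Counts, for every node incident to at least one significant edge, the
#' number of incident significant edges, and labels nodes through the
#' atlas. Rows are sorted by degree (descending), ties in atlas order.
#'
#' @param result an [edge_permutation_test()] result.
#' @param atlas atlas data.frame ([make_atlas()]).
#' @return data.frame (`region`, `hemisphere`, `degree`).
#' @export
degree_summary <- function(result, atlas) {
  stopifnot(inherits(result, "edge_test"))
  cent <- atlas[atlas$centroid, , drop = FALSE]
  cent <- cent[order(cent$roi), , drop = FALSE]
  deg <- tabulate(c(result$significant$node_i, result$significant$node_j),
                  nbins = result$n_nodes)
  keep <- which(deg > 0)
  out <- data.frame(region = cent$name[keep],
                    hemisphere = cent$hemisphere[keep],
                    degree = deg[keep], stringsAsFactors = FALSE)
  out[order(-out$degree, keep), , drop = FALSE]
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference on k-1 degrees of
#' freedom (delegating to [stats::kruskal.test()]); fully tied samples are
#' reported as H = 0, p = 1.
#'
#' @param groups list of >= 2 numeric vectors, each nonempty, total n >= 3.
#' @return list (`H`, `df`, `p`).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1), sum(lengths(groups)) >= 3)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (max(values) == min(values))
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  k <- kruskal.test(values, g)
  list(H = unname(k$statistic), df = unname(k$parameter),
       p = k$p.value)
}

#' Bonferroni-adjusted pairwise post hoc rank tests
#'
#' Wilcoxon rank-sum tests for every group pair with p-values multiplied by
#' the number of pairs (capped at 1).
#'
#' @param groups named list of >= 3 numeric vectors.
#' @param alpha significance level recorded alongside the table.
#' @return data.frame (`group_1`, `group_2`, `p_raw`, `p_adjusted`,
#'   `significant`).
#' @export
bonferroni_posthoc <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 3)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  pairs <- combn(names(groups), 2)
  npairs <- ncol(pairs)
  raw <- apply(pairs, 2, function(p) {
    x <- groups[[p[1]]]; y <- groups[[p[2]]]
    if (max(c(x, y)) == min(c(x, y))) return(1)
    suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  })
  data.frame(group_1 = pairs[1, ], group_2 = pairs[2, ],
             p_raw = raw, p_adjusted = pmin(1, raw * npairs),
             significant = pmin(1, raw * npairs) < alpha,
             stringsAsFactors = FALSE)
}
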
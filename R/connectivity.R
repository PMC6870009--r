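# Equal-width bin assignment over a signal's own observed range.
# Returns integer bins 1..bins, or NULL for a constant signal.
bin_assign <- function(x, bins) {
  mn <- min(x); mx <- max(x)
  if (mx <= mn) return(NULL)
  ix <- floor((x - mn) / (mx - mn) * bins) + 1L
  ix[ix > bins] <- bins
  as.integer(ix)
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p)) / log(2)                       # bits
}

#' Histogram plug-in entropies of two signals
#'
#' Equal-width histograms over each signal's own observed range, Shannon
#' entropies in bits; empty bins contribute nothing. A constant signal has
#' marginal entropy 0 and is flagged.
#'
#' @param x,y numeric sequences of equal length (>= 8).
#' @param bins number of bins per axis (>= 2).
#' @return list (`H_x`, `H_y`, `H_xy`, `bins`, `n`, `constant`).
#' @export
entropies <- function(x, y, bins) {
  stopifnot(length(x) == length(y), length(x) >= 8, bins >= 2)
  bins <- as.integer(bins)
  ix <- bin_assign(x, bins)
  iy <- bin_assign(y, bins)
  constant <- c(x = is.null(ix), y = is.null(iy))
  if (is.null(ix)) ix <- rep(1L, length(x))
  if (is.null(iy)) iy <- rep(1L, length(y))
  H_x <- entropy_from_counts(tabulate(ix, bins))
  H_y <- entropy_from_counts(tabulate(iy, bins))
  H_xy <- entropy_from_counts(tabulate(ix + bins * (iy - 1L), bins * bins))
  list(H_x = H_x, H_y = H_y, H_xy = H_xy, bins = bins, n = length(x),
       constant = constant)
}

#' Normalized mutual information of two signals
#'
#' Plug-in estimate \eqn{MI = H(S) + H(Q) - H(S,Q)} normalized by the
#' geometric mean of the marginal entropies, so identical signals score 1
#' and independent signals score near 0. An arithmetic-mean denominator is
#' available. If either marginal entropy is zero (constant signal) the NMI
#' is defined as 0, with a warning.
#'
#' @param x,y numeric sequences of equal length.
#' @param bins histogram bins per axis; default `min(32, ceiling(sqrt(n)))`
#'   (the square-root rule, capped so the plug-in bias (bins-1)^2/2n stays
#'   small for long signals).
#' @param denominator "geometric" (default) or "arithmetic".
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(x, y, bins = NULL,
                denominator = c("geometric", "arithmetic")) {
  denominator <- match.arg(denominator)
  if (is.null(bins)) bins <- min(32L, ceiling(sqrt(length(x))))
  e <- entropies(x, y, bins)
  nmi_from_entropies(e$H_x, e$H_y, e$H_xy, denominator, warn = TRUE)
}

nmi_from_entropies <- function(H_x, H_y, H_xy,
                               denominator = "geometric", warn = FALSE) {
  if (H_x <= 0 || H_y <= 0) {
    if (warn) warning("constant signal: NMI defined as 0")
    return(0)
  }
  mi <- H_x + H_y - H_xy
  den <- if (denominator == "geometric") sqrt(H_x * H_y) else (H_x + H_y) / 2
  min(1, max(0, mi / den))
}

#' Build the 80 x 80 NMI connectivity matrix of a ROI time series
#'
#' Computes the normalized mutual information of every unordered pair of
#' regions (C(80,2) = 3160 pairs for the standard atlas). The matrix is
#' symmetric with an exactly zero diagonal (self-connections excluded by
#' convention) and entries in `[0, 1]`.
#'
#' @param rois a `roi_ts` from [extract_roi()], or a regions x samples
#'   matrix.
#' @param bins histogram bins; default `min(32, ceiling(sqrt(n_samples)))`
#'   (8 for the 61-sample gating segments).
#' @param denominator see [nmi()].
#' @param subject subject identifier carried in the metadata.
#' @return object of class `connectivity_matrix`: `values` (n x n),
#'   `condition`, `subject`, `bins`, `n_samples`, `constant_rows`.
#' @export
build_connectivity <- function(rois, bins = NULL,
                               denominator = c("geometric", "arithmetic"),
                               subject = NA_character_) {
  denominator <- match.arg(denominator)
  X <- if (inherits(rois, "roi_ts")) rois$values else rois
  condition <- if (inherits(rois, "roi_ts")) rois$condition else NA_character_
  stopifnot(is.matrix(X), nrow(X) >= 2)
  n <- nrow(X)
  ns <- ncol(X)
  if (is.null(bins)) bins <- min(32L, ceiling(sqrt(ns)))
  bins <- as.integer(bins)
  if (ns < bins) stop("segment shorter than the bin count")
  idx <- vector("list", n)
  Hm <- numeric(n)
  for (r in seq_len(n)) {
    b <- bin_assign(X[r, ], bins)
    if (is.null(b)) b <- rep(1L, ns)
    idx[[r]] <- b
    Hm[r] <- entropy_from_counts(tabulate(b, bins))
  }
  constant_rows <- which(Hm <= 0)
  V <- matrix(0, n, n)
  b2 <- bins * bins
  for (i in seq_len(n - 1L)) {
    bi <- idx[[i]]
    for (j in seq.int(i + 1L, n)) {
      H_xy <- entropy_from_counts(tabulate(bi + bins * (idx[[j]] - 1L), b2))
      V[i, j] <- V[j, i] <- nmi_from_entropies(Hm[i], Hm[j], H_xy,
                                               denominator)
    }
  }
  dimnames(V) <- list(rownames(X), rownames(X))
  structure(list(values = V, condition = condition, subject = subject,
                 bins = bins, n_samples = ns,
                 constant_rows = constant_rows),
            class = "connectivity_matrix")
}

# Coerce a connectivity input (object or plain matrix) to its matrix.
conn_values <- function(W) {
  if (inherits(W, "connectivity_matrix")) W$values else W
}
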
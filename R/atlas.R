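#' Region-of-interest atlas for the synthetic source space
#'
#' Builds an AAL-style cortical atlas of 80 regions (40 per hemisphere).
#' Each region owns `sources_per_roi` dipole sources, one of which is flagged
#' as the centroid and represents the region downstream (the "central voxel"
#' rule). With the default of one source per region, centroid extraction is
#' the identity.
#'
#' @param sources_per_roi integer, dipoles per region (default 1).
#' @return data.frame with one row per source: `roi` (1..80), `name`,
#'   `hemisphere` ("L"/"R"), `source` (column index into the lead field) and
#'   `centroid` (logical).
#' @export
make_atlas <- function(sources_per_roi = 1L) {
  stopifnot(sources_per_roi >= 1L)
  base <- aal_region_names()
  roi <- data.frame(
    roi = seq_len(80L),
    name = rep(base, 2L),
    hemisphere = rep(c("L", "R"), each = 40L),
    stringsAsFactors = FALSE
  )
  out <- roi[rep(seq_len(80L), each = sources_per_roi), , drop = FALSE]
  out$source <- seq_len(nrow(out))
  out$centroid <- rep(c(TRUE, rep(FALSE, sources_per_roi - 1L)), times = 80L)
  rownames(out) <- NULL
  out
}

# 40 cortical region names per hemisphere, AAL-flavoured.
aal_region_names <- function() {
  c("Precentral gyrus", "Superior frontal gyrus",
    "Superior frontal gyrus, orbital part", "Middle frontal gyrus",
    "Middle orbitofrontal cortex", "Inferior frontal operculum",
    "Inferior frontal gyrus, triangular part",
    "Inferior frontal gyrus, orbital part", "Rolandic operculum",
    "Supplementary motor area", "Olfactory gyrus",
    "Superior frontal gyrus, medial part", "Media orbitofrontal cortex",
    "Gyrus rectus", "Insula", "Anterior cingulate cortex",
    "Middle cingulate cortex", "Posterior cingulate cortex", "Hippocampus",
    "Parahippocampal gyrus", "Amygdala", "Calcarine sulcus", "Cuneus",
    "Lingual gyrus", "Superior occipital gyrus", "Middle occipital gyrus",
    "Inferior occipital gyrus", "Fusiform gyrus", "Postcentral gyrus",
    "Superior parietal lobule", "Inferior parietal lobule",
    "Supramarginal gyrus", "Angular gyrus", "Precuneus",
    "Paracentral lobule", "Heschl gyrus", "Superior temporal gyrus",
    "Temporal pole, superior temporal gyrus", "Middle temporal gyrus",
    "Temporal pole, middle temporal gyrus")
}

#' Look up atlas rows by region name and hemisphere
#'
#' @param atlas atlas data.frame from [make_atlas()].
#' @param name region name (exact match).
#' @param hemisphere "L" or "R".
#' @return the ROI index (1..80).
#' @export
atlas_roi <- function(atlas, name, hemisphere) {
  hit <- which(atlas$name == name & atlas$hemisphere == hemisphere &
                 atlas$centroid)
  if (length(hit) != 1L)
    stop("atlas lookup failed for '", name, "' (", hemisphere, ")")
  atlas$roi[hit]
}

# Quasi-uniform points on a unit sphere cap (Fibonacci lattice), z >= zmin.
fibonacci_cap <- function(n, zmin, radius = 1) {
  golden <- (1 + sqrt(5)) / 2
  k <- seq_len(n) - 0.5
  z <- zmin + (1 - zmin) * (k / n)        # uniform in z over the cap
  phi <- 2 * pi * k / golden
  r <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Source positions: 40 quasi-uniform points on the x > 0 half of an inner
# shell (z > -0.45), mirrored to x < 0 for the left hemisphere. Row order
# matches make_atlas(): left block first, then right.
source_positions <- function(radius = 0.8) {
  pts <- fibonacci_cap(80L, zmin = -0.45, radius = radius)
  right <- pts[pts[, "x"] > 0, , drop = FALSE]
  # fibonacci alternates sides almost perfectly; top up deterministically
  if (nrow(right) > 40L) right <- right[seq_len(40L), , drop = FALSE]
  while (nrow(right) < 40L) {
    extra <- fibonacci_cap(97L, zmin = -0.45, radius = radius)
    extra <- extra[extra[, "x"] > 0, , drop = FALSE]
    right <- unique(rbind(right, extra))[seq_len(40L), , drop = FALSE]
  }
  left <- right
  left[, "x"] <- -left[, "x"]
  rbind(left, right)
}

#' Build a forward model (lead field) for the synthetic head
#'
#' The default "spherical" model places sensors on the upper cap of a
#' unit-radius quasi-spherical head and dipole sources on an inner shell,
#' and evaluates the homogeneous-conductor dipole potential
#' \eqn{v_i = q \cdot (r_i - p) / (4\pi |r_i - p|^3)} with a random dipole
#' orientation per source. A "gaussian" model (i.i.d. N(0,1) gain entries)
#' is available for unit tests. Columns are checked for degeneracy and the
#' matrix condition number is recorded.
#'
#' @param n_sensors number of sensors (rows).
#' @param atlas atlas data.frame; one gain column per atlas row.
#' @param type "spherical" or "gaussian".
#' @return list of class `lead_field`: `gain` (sensors x sources),
#'   `sensor_pos`, `source_pos`, `orientations`, `sensor_names`,
#'   `vertex_channels` (the 3 sensors nearest the vertex), `condition_number`.
#' @export
make_lead_field <- function(n_sensors = 32L, atlas = make_atlas(),
                            type = c("spherical", "gaussian")) {
  type <- match.arg(type)
  n_sources <- nrow(atlas)
  sensors <- fibonacci_cap(n_sensors, zmin = 0.05, radius = 1)
  vertex <- order(colSums((t(sensors) - c(0, 0, 1))^2))[seq_len(min(3L, n_sensors))]
  if (type == "gaussian") {
    gain <- matrix(rnorm(n_sensors * n_sources), n_sensors, n_sources)
    src <- NULL
    ori <- NULL
  } else {
    roi_pos <- source_positions()
    # per-source position: centroid at the ROI point, extra sources jittered
    src <- roi_pos[atlas$roi, , drop = FALSE]
    jitter <- matrix(rnorm(nrow(src) * 3, sd = 0.03), ncol = 3)
    jitter[atlas$centroid, ] <- 0
    src <- src + jitter
    ori <- matrix(rnorm(n_sources * 3), ncol = 3)
    ori <- ori / sqrt(rowSums(ori^2))
    gain <- matrix(0, n_sensors, n_sources)
    for (j in seq_len(n_sources)) {
      d <- sweep(sensors, 2, src[j, ])
      a <- d / (rowSums(d^2)^1.5 * 4 * pi)       # sensors x 3
      gain[, j] <- a %*% ori[j, ]
    }
  }
  if (any(!is.finite(gain)) || any(colSums(gain^2) < 1e-20))
    stop("degenerate lead field: non-finite or all-zero column")
  sv <- svd(gain, nu = 0, nv = 0)$d
  structure(list(
    gain = gain,
    sensor_pos = sensors,
    source_pos = src,
    orientations = ori,
    sensor_names = sprintf("E%03d", seq_len(n_sensors)),
    vertex_channels = vertex,
    condition_number = sv[1] / sv[min(nrow(gain), ncol(gain))],
    type = type
  ), class = "lead_field")
}
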
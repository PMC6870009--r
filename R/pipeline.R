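#' Process one subject through the ERP, inverse and connectivity stages
#'
#' Generates (or accepts) the subject's epochs, preprocesses them, scores
#' the sensor-level P50 on the vertex channel subset, reconstructs the
#' three condition segments in source space, and returns the per-condition
#' NMI networks and graph metrics. Raw epochs are not retained.
#'
#' @param design a [cohort_design()].
#' @param i subject index.
#' @param inv_op inverse operator from [fit_eloreta()] for the design's
#'   lead field.
#' @param band,reject_threshold_uv preprocessing settings
#'   ([preprocess_epochs()]).
#' @param min_s1_uv S1 exclusion threshold ([gating_measures()]).
#' @param bins NMI histogram bins ([build_connectivity()]).
#' @param density proportional threshold for the clustering coefficient.
#' @param epochs optionally, a precomputed raw [epoch_set()] for subject i.
#' @return list: `measures` (one-row data.frame), `networks` (list of
#'   `connectivity_matrix` for S1/S2/S1_S2), `metrics` (named length-9
#'   vector), `n_trials_retained`.
#' @export
process_subject <- function(design, i, inv_op, band = c(1, 40),
                            reject_threshold_uv = 100, min_s1_uv = 0.5,
                            bins = NULL, density = 0.2, epochs = NULL) {
  if (is.null(epochs)) epochs <- generate_subject_epochs(design, i)
  pp <- preprocess_epochs(epochs, band, reject_threshold_uv)
  em <- erp_measures(pp, channels = design$lead_field$vertex_channels,
                     min_s1_uv = min_s1_uv)
  networks <- list()
  for (cond in c("S1", "S2", "S1_S2")) {
    src <- apply_inverse(inv_op, em$segments[[cond]])
    roi <- extract_roi(src, design$atlas, condition = cond,
                       fs = epochs$fs)
    networks[[cond]] <- build_connectivity(roi, bins = bins,
                                           subject = design$subjects[i])
  }
  list(measures = em$measures, networks = networks,
       metrics = metrics_for_subject(networks, density),
       n_trials_retained = dim(pp$data)[1])
}

#' Run the full staging experiment on a synthetic cohort
#'
#' Streams every subject through [process_subject()], then performs the
#' group-level analyses: edge-wise permutation tests for the three group
#' pairs on each condition network, degree summaries, Kruskal-Wallis /
#' Bonferroni statistics of the P50 measures, and the three staging
#' classifiers (DEM+MCCB; +ERP; +NET) with repeated splits and stratified
#' fivefold cross-validation. Subjects failing the S1 exclusion rule are
#' flagged and skipped by the group statistics but kept in the feature
#' table.
#'
#' @param config a [synth_config()] (or a ready [cohort_design()]).
#' @param alpha_inverse regularization fraction for [fit_eloreta()].
#' @param band,reject_threshold_uv,min_s1_uv,bins,density see
#'   [process_subject()].
#' @param n_perm permutations per edge test (default 2000).
#' @param edge_alpha per-edge significance level.
#' @param n_rep repeated random splits (default 101).
#' @param seed seed for the permutation and classification stages (the
#'   cohort itself is governed by `config$seed`).
#' @param conditions conditions to run edge tests on.
#' @param verbose print progress.
#' @return object of class `gatenet_result`; see Details.
#' @details The returned list contains `erp` (per-subject P50 table),
#' `net` (per-subject graph metrics), `features` (the 24-feature table),
#' `networks` (per-subject condition networks), `edge_tests` (nested list
#' condition -> "A_vs_B" -> `edge_test`), `degree_tables`, `kruskal`
#' (per-measure Kruskal-Wallis + post hoc), `classifiers` (per feature
#' combination: `split_result` and `cv_result`), `importance_shares`,
#' `design`, and bookkeeping (`valid`, `seed`).
#' @export
run_pipeline <- function(config, alpha_inverse = 0.05, band = c(1, 40),
                         reject_threshold_uv = 100, min_s1_uv = 0.5,
                         bins = NULL, density = 0.2, n_perm = 2000L,
                         edge_alpha = 0.05, n_rep = 101L, seed = NULL,
                         conditions = c("S1", "S2", "S1_S2"),
                         verbose = FALSE) {
  design <- if (inherits(config, "cohort_design")) config
            else cohort_design(config)
  if (is.null(seed)) seed <- design$config$seed + 5000L
  n <- length(design$subjects)
  inv_op <- fit_eloreta(design$lead_field, alpha = alpha_inverse)

  erp_rows <- vector("list", n)
  metric_rows <- vector("list", n)
  networks <- vector("list", n)
  for (i in seq_len(n)) {
    if (verbose && (i %% 10 == 1))
      message("subject ", i, "/", n)
    ps <- process_subject(design, i, inv_op, band, reject_threshold_uv,
                          min_s1_uv, bins, density)
    erp_rows[[i]] <- ps$measures
    metric_rows[[i]] <- ps$metrics
    networks[[i]] <- ps$networks
  }
  erp <- do.call(rbind, erp_rows)
  erp$group <- design$labels
  net <- data.frame(subject = design$subjects,
                    do.call(rbind, metric_rows),
                    stringsAsFactors = FALSE, check.names = FALSE)
  valid <- erp$valid

  features <- assemble_features(erp, net, design$covariates)

  groups <- c("FESZ", "UHR", "HC")
  pair_list <- list(c("FESZ", "UHR"), c("FESZ", "HC"), c("UHR", "HC"))
  edge_tests <- list()
  degree_tables <- list()
  for (cond in conditions) {
    edge_tests[[cond]] <- list()
    degree_tables[[cond]] <- list()
    for (p in pair_list) {
      ia <- which(design$labels == p[1] & valid)
      ib <- which(design$labels == p[2] & valid)
      key <- paste(p, collapse = "_vs_")
      et <- edge_permutation_test(
        lapply(networks[ia], function(x) x[[cond]]),
        lapply(networks[ib], function(x) x[[cond]]),
        n_perm = n_perm, alpha = edge_alpha,
        seed = seed + length(edge_tests[[cond]]))
      edge_tests[[cond]][[key]] <- et
      degree_tables[[cond]][[key]] <- degree_summary(et, design$atlas)
    }
  }

  measure_cols <- c(s1_amp = "s1_amp", s2_amp = "s2_amp", diff = "diff",
                    ratio = "ratio")
  kruskal <- lapply(measure_cols, function(cl) {
    gl <- lapply(groups, function(g) {
      v <- erp[[cl]][erp$group == g & valid]
      v[is.finite(v)]
    })
    names(gl) <- groups
    list(test = kruskal_wallis(gl), posthoc = bonferroni_posthoc(gl))
  })

  combos <- list(
    "DEM_MCCB" = c("DEM", "MCCB"),
    "DEM_MCCB_ERP" = c("DEM", "MCCB", "ERP"),
    "DEM_MCCB_ERP_NET" = c("DEM", "MCCB", "ERP", "NET")
  )
  spec <- feature_spec()
  classifiers <- list()
  for (nm in names(combos)) {
    cols <- spec$feature[spec$class %in% combos[[nm]]]
    tab <- features[, c("subject", "group", cols), drop = FALSE]
    classifiers[[nm]] <- list(
      repeated = run_repeated(tab, n_rep = n_rep, seed = seed + 101L),
      fivefold = run_fivefold(tab, seed = seed + 202L)
    )
  }
  importance_shares <- feature_class_importance(
    classifiers$DEM_MCCB_ERP_NET$repeated$importance)

  structure(list(erp = erp, net = net, features = features,
                 networks = networks, edge_tests = edge_tests,
                 degree_tables = degree_tables, kruskal = kruskal,
                 classifiers = classifiers,
                 importance_shares = importance_shares,
                 design = design, valid = valid, seed = seed),
            class = "gatenet_result")
}

#' Number of significant edges per group pair
#'
#' @param result a `gatenet_result`.
#' @param condition condition network to summarize (default the gating
#'   segment "S1_S2").
#' @return named integer vector over group pairs.
#' @export
significant_edge_counts <- function(result, condition = "S1_S2") {
  vapply(result$edge_tests[[condition]],
         function(et) nrow(et$significant), integer(1))
}

#' Write the tabular products of a pipeline run to CSV files
#'
#' Writes the P50 measure table, graph-metric table, feature table, and the
#' per-pair significant-edge and degree tables of the chosen condition.
#'
#' @param result a `gatenet_result`.
#' @param dir output directory (created if needed).
#' @param condition condition for edge/degree tables.
#' @return invisibly, the written file paths.
#' @export
write_pipeline_csv <- function(result, dir, condition = "S1_S2") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    erp = file.path(dir, "p50_measures.csv"),
    net = file.path(dir, "network_metrics.csv"),
    features = file.path(dir, "features.csv")
  )
  write.csv(result$erp, paths["erp"], row.names = FALSE)
  write.csv(result$net, paths["net"], row.names = FALSE)
  write.csv(result$features, paths["features"], row.names = FALSE)
  for (key in names(result$edge_tests[[condition]])) {
    p1 <- file.path(dir, paste0("edges_", condition, "_", key, ".csv"))
    p2 <- file.path(dir, paste0("degrees_", condition, "_", key, ".csv"))
    write.csv(result$edge_tests[[condition]][[key]]$significant, p1,
              row.names = FALSE)
    write.csv(result$degree_tables[[condition]][[key]], p2,
              row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
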
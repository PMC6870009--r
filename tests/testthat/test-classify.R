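# Build a feature table directly (no pipeline) with controllable signal.
fake_table <- function(n = c(FESZ = 25, UHR = 23, HC = 19), sep = 0,
                       net_sep = 0, seed = 1) {
  set.seed(seed)
  groups <- rep(names(n), n)
  ns <- length(groups)
  gi <- match(groups, names(n))
  spec <- feature_spec()
  out <- data.frame(subject = sprintf("S%03d", seq_len(ns)),
                    group = factor(groups, levels = c("FESZ", "UHR", "HC")))
  for (f in spec$feature) {
    base <- rnorm(ns)
    if (spec$class[spec$feature == f] == "NET")
      base <- base + net_sep * gi
    else if (f %in% c("AVV", "SOPV"))
      base <- base + sep * gi
    out[[f]] <- base
  }
  out
}

test_that("feature table assembly joins the three sources into 24 columns", {
  cfg <- synth_config(seed = 12)
  cov <- generate_feature_covariates(cfg)
  ids <- cov$subject
  set.seed(1)
  erp <- data.frame(subject = ids, s1_amp = rnorm(67, 1.2, 0.3),
                    s2_amp = rnorm(67, 0.8, 0.3), diff = rnorm(67),
                    ratio = runif(67), valid = TRUE)
  net <- data.frame(subject = ids, matrix(rnorm(67 * 9), 67,
                    dimnames = list(NULL, feature_spec()$feature[5:13])),
                    check.names = FALSE)
  tab <- assemble_features(erp, net, cov)
  expect_equal(nrow(tab), 67L)
  expect_equal(setdiff(names(tab), c("subject", "group")),
               feature_spec()$feature)     # 24 features, canonical order
  expect_equal(unname(table(feature_spec()$class)[c("ERP", "NET", "DEM", "MCCB")]),
               c(4L, 9L, 3L, 8L), ignore_attr = TRUE)
  # row order of the inputs does not matter
  tab2 <- assemble_features(erp[sample(67), ], net[rev(seq_len(67)), ], cov)
  expect_equal(tab, tab2)
  expect_error(assemble_features(erp[-3, ], net, cov), "S003")
})

test_that("20%-per-group splits give the published 14/53 partition", {
  labels <- rep(c("FESZ", "UHR", "HC"), c(25, 23, 19))
  sp <- split_20pct_per_group(labels, seed = 4)
  expect_length(sp$test, 14L)
  expect_length(sp$train, 53L)
  expect_equal(sum(labels[sp$test] == "FESZ"), 5L)
  expect_equal(sum(labels[sp$test] == "UHR"), 5L)
  expect_equal(sum(labels[sp$test] == "HC"), 4L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  even <- split_20pct_per_group(rep(c("A", "B", "C"), each = 10), seed = 1)
  expect_length(even$test, 6L)
})

test_that("stratified folds partition 67 subjects into 13/13/13/14/14", {
  labels <- rep(c("FESZ", "UHR", "HC"), c(25, 23, 19))
  fold <- gatenet:::stratified_folds(labels, 5, seed = 3)
  expect_equal(sort(tabulate(fold, 5)), c(13, 13, 13, 14, 14))
  for (g in unique(labels)) {
    per <- tabulate(fold[labels == g], 5)
    expect_lte(max(per) - min(per), 1)    # within one subject per fold
  }
  expect_identical(fold, gatenet:::stratified_folds(labels, 5, seed = 3))
})

test_that("separable features reach near-perfect accuracy; shuffled labels are at chance", {
  tab <- fake_table(sep = 8, seed = 2)
  res <- run_repeated(tab, n_rep = 21, seed = 5)
  expect_length(res$accuracies, 21L)
  expect_gte(res$median_accuracy, 0.95)
  expect_equal(sum(res$confusion_median), 14)   # per-group test counts
  # chance level for three shuffled groups
  accs <- vapply(1:5, function(s) {
    t2 <- fake_table(sep = 8, seed = 2)
    set.seed(100 + s)
    t2$group <- sample(t2$group)
    run_repeated(t2, n_rep = 15, seed = s)$median_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.15)
})

test_that("repeated runs are deterministic and report 101 accuracies by default", {
  tab <- fake_table(sep = 2, seed = 3)
  r1 <- run_repeated(tab, n_rep = 101, seed = 7)
  r2 <- run_repeated(tab, n_rep = 101, seed = 7)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_length(r1$accuracies, 101L)
  expect_equal(r1$median_accuracy, sort(r1$accuracies)[51])
  expect_true(all(r1$accuracies >= 0 & r1$accuracies <= 1))
})

test_that("fivefold CV covers every subject once and is seed-stable", {
  tab <- fake_table(sep = 4, seed = 4)
  cv <- run_fivefold(tab, seed = 11)
  expect_equal(sort(cv$fold_sizes), c(13, 13, 13, 14, 14))
  expect_length(cv$fold_accuracies, 5L)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  cv2 <- run_fivefold(tab, seed = 11)
  expect_identical(cv$fold_accuracies, cv2$fold_accuracies)
})

test_that("degenerate all-identical features fall back to majority-rate accuracy", {
  tab <- fake_table(seed = 5)
  for (f in feature_spec()$feature) tab[[f]] <- 1
  expect_error(run_repeated(tab, n_rep = 3, seed = 1), NA)
})

test_that("importance shares sum to 100 and land on the signal class", {
  vi <- c(AVV = 3, SOPV = 1)                      # single-class importance
  sh <- feature_class_importance(vi)
  expect_equal(sum(sh), 100)
  expect_equal(unname(sh["MCCB"]), 100)
  hits <- 0
  for (s in 1:10) {
    tab <- fake_table(net_sep = 6, seed = 200 + s)
    res <- run_repeated(tab, n_rep = 11, seed = s)
    sh <- feature_class_importance(res$importance)
    expect_equal(sum(sh), 100, tolerance = 1e-9)
    if (which.max(sh) == which(names(sh) == "NET")) hits <- hits + 1
  }
  expect_gte(hits, 9)                             # NET carries the signal
})
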
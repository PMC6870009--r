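#' Canonical feature set of the staging classifier
#'
#' The 24 features, in canonical column order, partitioned into the four
#' feature classes: ERP (S1_Amplitude, S2_Amplitude, S1_S2 = amplitude
#' difference, S2_S1 = suppression ratio), NET (the 9 graph metrics), DEM
#' (gender, age, education) and MCCB (the 8 cognitive scores).
#'
#' @return data.frame with columns `feature` and `class`.
#' @export
feature_spec <- function() {
  data.frame(
    feature = c("S1_Amplitude", "S2_Amplitude", "S1_S2", "S2_S1",
                "S1_CLU", "S2_CLU", "S1_S2_CLU",
                "S1_CHA", "S2_CHA", "S1_S2_CHA",
                "S1_EFF", "S2_EFF", "S1_S2_EFF",
                "gender", "age", "education",
                "SOPV", "AVV", "WMV", "VBLV", "VSLV", "RPSV", "SCV", "OCV"),
    class = rep(c("ERP", "NET", "DEM", "MCCB"), c(4L, 9L, 3L, 8L)),
    stringsAsFactors = FALSE
  )
}

#' Assemble the 24-feature staging table
#'
#' Joins per-subject ERP measures, network metrics and covariates on the
#' subject id into the canonical 24-column feature table plus the group
#' label. All three sources must cover exactly the same subjects.
#'
#' @param erp data.frame with `subject`, `s1_amp`, `s2_amp`, `diff`,
#'   `ratio` (as written by the ERP stage).
#' @param net data.frame with `subject` and the 9 graph-metric columns.
#' @param covariates data.frame with `subject`, `group`, `gender`, `age`,
#'   `education` and the 8 MCCB columns.
#' @return data.frame: `subject`, `group` (factor FESZ/UHR/HC), then the 24
#'   features in canonical order.
#' @export
assemble_features <- function(erp, net, covariates) {
  for (d in list(erp, net, covariates))
    if (!"subject" %in% names(d)) stop("every source needs a subject column")
  ids <- sort(covariates$subject)
  for (nm in c("erp", "net")) {
    d <- get(nm)
    miss <- union(setdiff(ids, d$subject), setdiff(d$subject, ids))
    if (length(miss))
      stop("subjects not shared by all sources: ",
           paste(miss, collapse = ", "))
  }
  erp <- erp[match(ids, erp$subject), , drop = FALSE]
  net <- net[match(ids, net$subject), , drop = FALSE]
  cov <- covariates[match(ids, covariates$subject), , drop = FALSE]
  out <- data.frame(
    subject = ids,
    group = factor(cov$group, levels = c("FESZ", "UHR", "HC")),
    S1_Amplitude = erp$s1_amp, S2_Amplitude = erp$s2_amp,
    S1_S2 = erp$diff, S2_S1 = erp$ratio,
    stringsAsFactors = FALSE
  )
  for (f in feature_spec()$feature[5:13]) out[[f]] <- net[[f]]
  for (f in c("gender", "age", "education",
              "SOPV", "AVV", "WMV", "VBLV", "VSLV", "RPSV", "SCV", "OCV"))
    out[[f]] <- cov[[f]]
  if (anyNA(out$group)) stop("missing group labels")
  out
}

#' Random 20%-per-group test split
#'
#' Draws, within each group, the nearest integer to 20% of its subjects for
#' testing (at least 1), the remainder for training: 25/23/19 subjects
#' split into 14 test and 53 training samples.
#'
#' @param labels vector of group labels (one per subject).
#' @param seed optional integer seed.
#' @return list (`train`, `test`) of subject indices.
#' @export
split_20pct_per_group <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  test <- integer(0)
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) < 5) stop("need at least 5 subjects per group")
    n_test <- max(1L, round(0.2 * length(idx)))
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

# Grow a full classification tree and post-prune by cost complexity, with
# the penalty chosen on rpart's internal cross-validation error.
fit_pruned_tree <- function(data, xval = 5L, minsplit = 8L, minbucket = 3L) {
  if (length(unique(data$group)) < 2)
    stop("degenerate training set: single class")
  fit <- rpart::rpart(group ~ ., data = data, method = "class",
                      control = rpart::rpart.control(cp = 0, xval = xval,
                                                     minsplit = minsplit,
                                                     minbucket = minbucket))
  cpt <- fit$cptable
  best <- cpt[which.min(cpt[, "xerror"]), "CP"]   # ties -> larger cp
  rpart::prune(fit, cp = best)
}

#' Repeated random-split evaluation of the staging tree
#'
#' Repeats `n_rep` times: draw a fresh 20%-per-group test split, grow and
#' post-prune a decision tree on the training samples (cost-complexity
#' pruning selected by internal fivefold cross-validation), and score the
#' test accuracy. The headline value is the median of the accuracies (the
#' 51st order statistic for 101 repetitions); the confusion matrix of the
#' first repetition attaining the median is kept.
#'
#' @param features feature table from [assemble_features()]; any subset of
#'   feature columns may be supplied (the `subject` column is ignored for
#'   fitting).
#' @param n_rep repetitions (default 101).
#' @param seed master seed; each repetition draws its own split and tree.
#' @param xval,minsplit,minbucket tree-growing controls.
#' @return object of class `split_result`: `accuracies`,
#'   `median_accuracy`, `mean_accuracy`, `sd_accuracy`,
#'   `confusion_median` (rows = true groups at the median repetition),
#'   `per_group_correct`, `importance` (summed impurity importance across
#'   repetitions), `seed`.
#' @export
run_repeated <- function(features, n_rep = 101L, seed = 1L, xval = 5L,
                         minsplit = 8L, minbucket = 3L) {
  stopifnot(n_rep >= 1)
  dat <- features[, setdiff(names(features), "subject"), drop = FALSE]
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  acc <- numeric(n_rep)
  confusions <- vector("list", n_rep)
  importance <- numeric(0)
  for (r in seq_len(n_rep)) {
    set.seed(rep_seeds[r])
    sp <- split_20pct_per_group(dat$group)
    fit <- fit_pruned_tree(dat[sp$train, , drop = FALSE], xval, minsplit,
                           minbucket)
    pred <- predict(fit, dat[sp$test, , drop = FALSE], type = "class")
    truth <- dat$group[sp$test]
    acc[r] <- mean(pred == truth)
    confusions[[r]] <- table(truth = truth, predicted = pred)
    vi <- fit$variable.importance
    if (length(vi)) {
      for (f in names(vi))
        importance[f] <- (if (f %in% names(importance)) importance[f] else 0) + vi[f]
    }
  }
  med <- sort(acc)[ceiling(n_rep / 2)]            # lower median for even n
  med_idx <- which(acc == med)[1]
  cm <- confusions[[med_idx]]
  structure(list(accuracies = acc, median_accuracy = med,
                 mean_accuracy = mean(acc), sd_accuracy = sd(acc),
                 confusion_median = cm,
                 per_group_correct = diag(as.matrix(cm)),
                 importance = importance, seed = seed),
            class = "split_result")
}

# Stratified k-fold assignment balancing total fold sizes: each group is
# spread as evenly as possible, remainders go to the currently smallest
# folds. 67 = 25 + 23 + 19 subjects yield folds of 13, 13, 13, 14, 14.
stratified_folds <- function(labels, k = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  totals <- numeric(k)
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    n <- length(idx)
    base <- n %/% k
    counts <- rep(base, k)
    extra <- n %% k
    if (extra > 0) {
      give <- order(totals, seq_len(k))[seq_len(extra)]
      counts[give] <- counts[give] + 1L
    }
    fold[idx] <- rep(seq_len(k), counts)
    totals <- totals + counts
  }
  fold
}

#' Stratified fivefold cross-validation of the staging tree
#'
#' Partitions subjects into `k` folds preserving per-group proportions
#' (within one subject), trains a post-pruned tree on k-1 folds and tests
#' on the held-out fold, and averages the `k` accuracies.
#'
#' @inheritParams run_repeated
#' @param k number of folds (default 5).
#' @return object of class `cv_result`: `fold_accuracies`,
#'   `mean_accuracy`, `fold_sizes`, `seed`.
#' @export
run_fivefold <- function(features, seed = 1L, k = 5L, xval = 5L,
                         minsplit = 8L, minbucket = 3L) {
  dat <- features[, setdiff(names(features), "subject"), drop = FALSE]
  fold <- stratified_folds(dat$group, k, seed)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    fit <- fit_pruned_tree(dat[fold != f, , drop = FALSE], xval, minsplit,
                           minbucket)
    pred <- predict(fit, dat[fold == f, , drop = FALSE], type = "class")
    acc[f] <- mean(pred == dat$group[fold == f])
  }
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 fold_sizes = tabulate(fold, k), seed = seed),
            class = "cv_result")
}

#' Feature-class importance shares
#'
#' Sums impurity-decrease variable importance within each feature class
#' (ERP, NET, DEM, MCCB) and normalizes to percentages.
#'
#' @param importance named numeric vector of per-feature importance (e.g.
#'   the `importance` element of [run_repeated()]), or a list of fitted
#'   rpart trees whose importances are summed first.
#' @return named numeric vector of percentage shares (sums to 100).
#' @export
feature_class_importance <- function(importance) {
  if (is.list(importance) && !is.numeric(importance)) {
    acc <- numeric(0)
    for (fit in importance) {
      vi <- fit$variable.importance
      for (f in names(vi))
        acc[f] <- (if (f %in% names(acc)) acc[f] else 0) + vi[f]
    }
    importance <- acc
  }
  spec <- feature_spec()
  shares <- vapply(c("ERP", "NET", "DEM", "MCCB"), function(cl) {
    feats <- spec$feature[spec$class == cl]
    sum(importance[intersect(names(importance), feats)])
  }, numeric(1))
  if (sum(shares) <= 0) stop("no importance mass on known features")
  100 * shares / sum(shares)
}
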
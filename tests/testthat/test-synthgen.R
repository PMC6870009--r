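test_that("same seed gives bit-identical cohorts, different seeds differ", {
  cfg <- tiny_config(seed = 5L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$epochs[[2]]$data, c2$epochs[[2]]$data)
  expect_identical(c1$covariates, c2$covariates)
  c3 <- generate_cohort(tiny_config(seed = 6L))
  expect_false(identical(c1$epochs[[2]]$data, c3$epochs[[2]]$data))
})

test_that("noiseless sensor data are the lead-field columns times the source waveform", {
  cfg <- synth_config(n_per_group = c(FESZ = 1, UHR = 1, HC = 1),
                      n_trials = 2, n_sensors = 12, noise_sd = 0,
                      sensor_noise_sd = 0, planted_edges = NULL, seed = 3)
  des <- cohort_design(cfg)
  ep <- generate_subject_epochs(des, 1)
  times <- ep$times_ms
  burst <- function(peak) exp(-(times - peak)^2 / (2 * cfg$burst_sd_ms^2))
  wave <- des$s1_amp[1] * burst(50) + des$s2_amp[1] * burst(550)
  G <- des$lead_field$gain
  expected <- G[, des$auditory_sources[1]] %o% wave +
    G[, des$auditory_sources[2]] %o% wave
  expect_equal(ep$data[1, , ], expected, tolerance = 1e-10)
  expect_identical(ep$data[1, , ], ep$data[2, , ])
})

test_that("forward model is linear: doubling source amplitudes doubles noiseless data", {
  base <- list(n_per_group = c(FESZ = 1, UHR = 1, HC = 1), n_trials = 1,
               n_sensors = 10, noise_sd = 0, sensor_noise_sd = 0,
               planted_edges = NULL, seed = 9)
  amp <- default_amp_params()
  c1 <- do.call(synth_config, base)
  amp2 <- list(s1 = amp$s1 * 2, s2 = amp$s2 * 2)
  amp2$s1["sd", ] <- 0; amp2$s2["sd", ] <- 0
  amp1 <- list(s1 = amp$s1, s2 = amp$s2)
  amp1$s1["sd", ] <- 0; amp1$s2["sd", ] <- 0
  e1 <- generate_subject_epochs(cohort_design(
    do.call(synth_config, c(base, list(s1_amp_mean_sd = amp1$s1,
                                       s2_amp_mean_sd = amp1$s2)))), 1)
  e2 <- generate_subject_epochs(cohort_design(
    do.call(synth_config, c(base, list(s1_amp_mean_sd = amp2$s1,
                                       s2_amp_mean_sd = amp2$s2)))), 1)
  expect_equal(2 * e1$data, e2$data, tolerance = 1e-10)
})

test_that("atlas has 80 regions, 40 per hemisphere, with unique centroids", {
  atlas <- make_atlas()
  expect_equal(nrow(atlas), 80L)
  expect_equal(unname(table(atlas$hemisphere)), c(40L, 40L),
               ignore_attr = TRUE)
  expect_true(all(atlas$centroid))
  dense <- make_atlas(sources_per_roi = 3L)
  expect_equal(nrow(dense), 240L)
  expect_equal(sum(dense$centroid), 80L)
  expect_true(all(tapply(dense$centroid, dense$roi, sum) == 1))
})

test_that("lead field is finite, non-degenerate and reports its conditioning", {
  set.seed(2)
  lf <- make_lead_field(24L, make_atlas(), "spherical")
  expect_true(all(is.finite(lf$gain)))
  expect_true(all(colSums(lf$gain^2) > 0))
  expect_true(is.finite(lf$condition_number) && lf$condition_number >= 1)
  expect_length(lf$vertex_channels, 3L)
})

test_that("invalid planted edges are rejected", {
  bad <- data.frame(roi_i = 5, roi_j = 99, FESZ = 0.5, UHR = 0.5, HC = 0)
  expect_error(tiny_config(planted_edges = bad), "outside the 80-region")
  bad2 <- data.frame(roi_i = 5, roi_j = 7, FESZ = 1.4, UHR = 0, HC = 0)
  expect_error(tiny_config(planted_edges = bad2), "\\[0, 1\\]")
})

test_that("covariate table has one row per subject with plausible values", {
  cfg <- synth_config(n_per_group = c(FESZ = 25, UHR = 23, HC = 19),
                      seed = 21)
  cov <- generate_feature_covariates(cfg)
  expect_equal(nrow(cov), 67L)
  expect_equal(unname(table(cov$group)[c("FESZ", "UHR", "HC")]),
               c(25L, 23L, 19L), ignore_attr = TRUE)
  mccb <- c("SOPV", "AVV", "WMV", "VBLV", "VSLV", "RPSV", "SCV", "OCV")
  expect_true(all(as.matrix(cov[, mccb]) >= 0))
  expect_true(all(cov$gender %in% c(0, 1)))
  expect_identical(cov, generate_feature_covariates(cfg))
})

test_that("zero-SD covariates collapse to the group means", {
  cp <- default_covariate_params()
  for (v in names(cp$mean_sd)) cp$mean_sd[[v]]["sd", ] <- 0
  cfg <- tiny_config(covariate_params = cp)
  cov <- generate_feature_covariates(cfg)
  for (g in c("FESZ", "UHR", "HC")) {
    rows <- cov$group == g
    expect_equal(unique(cov$AVV[rows]), cp$mean_sd$AVV["mean", g])
    expect_equal(unique(cov$age[rows]), cp$mean_sd$age["mean", g])
  }
})

test_that("control-group attention/vigilance means recover the configured 47.79", {
  means <- vapply(1:30, function(s) {
    cfg <- synth_config(n_per_group = c(FESZ = 1, UHR = 1, HC = 19),
                        seed = 100 + s)
    cov <- generate_feature_covariates(cfg)
    mean(cov$AVV[cov$group == "HC"])
  }, numeric(1))
  sem <- 8.80 / sqrt(19 * 30)
  expect_lt(abs(mean(means) - 47.79), 2 * sem)
})

test_that("group-mean S1 amplitude survives the ERP stage", {
  # 12 patients at the published FESZ amplitude parameters
  cfg <- synth_config(n_per_group = c(FESZ = 12, UHR = 1, HC = 1),
                      n_trials = 80, n_sensors = 32, seed = 31)
  des <- cohort_design(cfg)
  inv <- fit_eloreta(des$lead_field, 0.05)
  idx <- which(des$labels == "FESZ")
  s1 <- vapply(idx, function(i) {
    ep <- preprocess_epochs(generate_subject_epochs(des, i))
    m <- erp_measures(ep, channels = des$lead_field$vertex_channels)
    m$measures$s1_amp
  }, numeric(1))
  # two-SEM check on the sample mean (empirical SEM: the measured
  # amplitudes carry estimation noise on top of the configured 0.58 SD)
  expect_lt(abs(mean(s1) - 1.24), 2 * sd(s1) / sqrt(length(s1)))
  # the measurement tracks each subject's configured amplitude; the
  # tolerance covers peak-picking noise bias plus the (real) contribution
  # of planted gating-window activity leaking into the vertex channels
  expect_lt(abs(mean(s1 - des$s1_amp[idx])), 0.6)
})

test_that("raising a planted coupling raises that edge's downstream NMI", {
  run_edge_nmi <- function(coupling, seed) {
    pe <- data.frame(roi_i = 10, roi_j = 55, FESZ = coupling,
                     UHR = coupling, HC = coupling)
    cfg <- synth_config(n_per_group = c(FESZ = 1, UHR = 1, HC = 1),
                        n_trials = 40, n_sensors = 32,
                        planted_edges = pe, seed = seed)
    des <- cohort_design(cfg)
    inv <- fit_eloreta(des$lead_field, 0.05)
    ps <- process_subject(des, 1, inv)
    ps$networks$S1_S2$values[10, 55]
  }
  lo <- vapply(1:20, function(s) run_edge_nmi(0.1, 700 + s), numeric(1))
  hi <- vapply(1:20, function(s) run_edge_nmi(1.0, 700 + s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})
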
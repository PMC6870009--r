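#' Configuration for a synthetic three-group P50 cohort
#'
#' Encodes the study conditions of a paired-click sensory-gating cohort:
#' group sizes, the paradigm timing (S1 at 0 ms, S2 at +500 ms, epochs
#' -200..+1000 ms, 1000 Hz), per-group P50 source amplitudes, planted
#' cross-region coupling and covariate distributions. Defaults are the
#' published group means/SDs of the cognition subsample (25 FESZ, 23 UHR,
#' 19 HC).
#'
#' @param n_per_group named integer vector `c(FESZ=, UHR=, HC=)`.
#' @param n_trials click-pair trials per subject.
#' @param fs sampling rate (Hz).
#' @param n_sensors EEG channel count (up to 128).
#' @param sources_per_roi dipoles per region; the first is the centroid.
#' @param s1_amp_mean_sd,s2_amp_mean_sd 2 x 3 matrices (rows mean/sd,
#'   columns FESZ/UHR/HC) of P50 source amplitudes in microvolt.
#' @param planted_edges data.frame with columns `roi_i`, `roi_j`, `FESZ`,
#'   `UHR`, `HC` (coupling strengths in `[0,1]`); see Details.
#' @param noise_sd per-source 1/f background noise SD (microvolt).
#' @param sensor_noise_sd spatially white sensor noise SD (microvolt).
#' @param planted_amp_uv RMS amplitude (microvolt) of a fully coupled
#'   (coupling 1) planted evoked latent within its window; the scale of
#'   the published gating-difference amplitudes.
#' @param covariate_params per-group covariate means/SDs, see
#'   [default_covariate_params()].
#' @param lead_field_type "spherical" (analytic dipole model) or "gaussian".
#' @param epoch_ms epoch span around S1 onset, milliseconds.
#' @param s2_offset_ms S2 click latency after S1 (ms).
#' @param burst_sd_ms Gaussian width of the P50 burst (ms).
#' @param burst_peak_ms P50 burst peak latency after each click (ms).
#' @param seed integer RNG seed; equal seeds give bit-identical cohorts.
#'
#' @details A planted edge couples two regions through a shared
#' trial-locked (evoked) latent waveform: for each click window a smooth
#' random waveform is drawn once per subject, tapered to the 30-90 ms
#' post-click window, and injected identically into both ROI sources on
#' every trial with amplitude `coupling * planted_amp_uv`. Trial-locked
#' injection is essential because the downstream connectivity analysis
#' works on trial-averaged segments, which cancel any non-phase-locked
#' activity. Edge indices outside the 80-region atlas and couplings
#' outside `[0,1]` are rejected.
#'
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_per_group = c(FESZ = 25L, UHR = 23L, HC = 19L),
                         n_trials = 80L, fs = 1000, n_sensors = 32L,
                         sources_per_roi = 1L,
                         s1_amp_mean_sd = default_amp_params()$s1,
                         s2_amp_mean_sd = default_amp_params()$s2,
                         planted_edges = default_planted_edges(),
                         noise_sd = 1, sensor_noise_sd = 0.5,
                         planted_amp_uv = 0.5,
                         covariate_params = default_covariate_params(),
                         lead_field_type = "spherical",
                         epoch_ms = c(-200, 1000), s2_offset_ms = 500,
                         burst_sd_ms = 12, burst_peak_ms = 50,
                         seed = 1L) {
  groups <- c("FESZ", "UHR", "HC")
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  stopifnot(identical(names(n_per_group), groups),
            all(n_per_group > 0), n_trials > 0, fs > 0,
            n_sensors >= 4, sources_per_roi >= 1,
            noise_sd >= 0, sensor_noise_sd >= 0,
            epoch_ms[1] <= -200, epoch_ms[2] >= 1000)
  n_sources <- 80L * as.integer(sources_per_roi)
  pe <- planted_edges
  if (!is.null(pe) && nrow(pe)) {
    stopifnot(all(c("roi_i", "roi_j", groups) %in% names(pe)))
    if (any(pe$roi_i < 1 | pe$roi_i > 80 | pe$roi_j < 1 | pe$roi_j > 80))
      stop("planted edge references a ROI outside the 80-region atlas")
    cc <- as.matrix(pe[, groups])
    if (any(cc < 0 | cc > 1)) stop("coupling strengths must lie in [0, 1]")
  }
  structure(list(
    n_per_group = n_per_group, n_trials = as.integer(n_trials), fs = fs,
    n_sensors = as.integer(n_sensors),
    sources_per_roi = as.integer(sources_per_roi), n_sources = n_sources,
    s1_amp_mean_sd = s1_amp_mean_sd, s2_amp_mean_sd = s2_amp_mean_sd,
    planted_edges = pe, noise_sd = noise_sd,
    sensor_noise_sd = sensor_noise_sd,
    planted_amp_uv = planted_amp_uv,
    covariate_params = covariate_params,
    lead_field_type = lead_field_type,
    epoch_ms = epoch_ms, s2_offset_ms = s2_offset_ms,
    burst_sd_ms = burst_sd_ms, burst_peak_ms = burst_peak_ms,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Published per-group P50 source amplitude parameters (microvolt)
#' @return list of 2 x 3 matrices `s1`, `s2` (rows mean/sd; columns
#'   FESZ/UHR/HC).
#' @export
default_amp_params <- function() {
  mk <- function(v) matrix(v, 2, 3, dimnames = list(c("mean", "sd"),
                                                    c("FESZ", "UHR", "HC")))
  list(s1 = mk(c(1.24, 0.58, 1.13, 0.73, 1.30, 0.90)),
       s2 = mk(c(0.99, 0.61, 0.67, 0.43, 0.74, 0.56)))
}

#' Per-group covariate distributions (age, education, gender, 8 MCCB scores)
#'
#' Means and SDs follow the published cognition-subsample table; gender is a
#' Bernoulli female rate per group (13/25, 12/23, 8/19).
#' @return list with `mean_sd` (named list of 2 x 3 matrices) and
#'   `female_rate` (length-3 vector).
#' @export
default_covariate_params <- function() {
  mk <- function(v) matrix(v, 2, 3, dimnames = list(c("mean", "sd"),
                                                    c("FESZ", "UHR", "HC")))
  list(
    mean_sd = list(
      age       = mk(c(25.09, 6.44, 22.67, 5.38, 25.45, 2.90)),
      education = mk(c(12.74, 3.08, 13.37, 3.12, 14.38, 3.14)),
      SOPV = mk(c(33.28, 9.22, 36.96, 7.21, 41.68, 6.38)),
      AVV  = mk(c(31.91, 10.63, 39.53, 9.04, 47.79, 8.80)),
      WMV  = mk(c(37.24, 10.01, 40.70, 9.35, 44.84, 8.07)),
      VBLV = mk(c(39.12, 9.83, 42.74, 10.08, 46.58, 9.34)),
      VSLV = mk(c(40.96, 13.77, 44.04, 10.22, 43.89, 10.07)),
      RPSV = mk(c(34.32, 11.87, 37.74, 9.21, 40.37, 10.16)),
      SCV  = mk(c(30.80, 11.79, 38.55, 7.90, 37.00, 11.06)),
      OCV  = mk(c(35.22, 7.08, 39.83, 6.02, 42.88, 6.40))
    ),
    female_rate = c(FESZ = 13 / 25, UHR = 12 / 23, HC = 8 / 19)
  )
}

#' Default planted connectivity differences
#'
#' Twenty-four region pairs following the published gating-stage group
#' differences (the top connections of the patient-vs-control comparison,
#' with the paracentral lobule, middle temporal gyrus, insula and
#' orbital/opercular frontal cortex as hubs), coupled at 0.9 in both
#' patient groups and 0 in controls: patient-vs-control comparisons carry
#' planted signal, the FESZ-vs-UHR comparison carries none.
#' @param coupling coupling strength for the patient groups.
#' @return data.frame usable as `planted_edges` in [synth_config()].
#' @export
default_planted_edges <- function(coupling = 0.9) {
  atlas <- make_atlas()
  pairs <- list(
    c("Paracentral lobule", "R", "Middle temporal gyrus", "R"),
    c("Paracentral lobule", "R", "Inferior frontal operculum", "L"),
    c("Superior frontal gyrus", "R", "Middle temporal gyrus", "R"),
    c("Paracentral lobule", "R", "Temporal pole, middle temporal gyrus", "R"),
    c("Paracentral lobule", "L", "Temporal pole, middle temporal gyrus", "R"),
    c("Paracentral lobule", "R", "Insula", "L"),
    c("Precentral gyrus", "L", "Middle temporal gyrus", "R"),
    c("Paracentral lobule", "L", "Middle temporal gyrus", "R"),
    c("Paracentral lobule", "L", "Superior frontal gyrus", "L"),
    c("Paracentral lobule", "R", "Rolandic operculum", "L"),
    c("Paracentral lobule", "L", "Inferior frontal operculum", "L"),
    c("Paracentral lobule", "R", "Media orbitofrontal cortex", "R"),
    c("Insula", "L", "Middle temporal gyrus", "R"),
    c("Paracentral lobule", "R", "Inferior parietal lobule", "L"),
    c("Insula", "L", "Posterior cingulate cortex", "L"),
    c("Paracentral lobule", "L", "Superior frontal gyrus, orbital part", "L"),
    c("Paracentral lobule", "L", "Inferior parietal lobule", "L"),
    c("Insula", "L", "Media orbitofrontal cortex", "R"),
    c("Middle temporal gyrus", "L", "Posterior cingulate cortex", "R"),
    c("Inferior frontal operculum", "L", "Media orbitofrontal cortex", "R"),
    c("Paracentral lobule", "R", "Superior frontal gyrus", "L"),
    c("Inferior frontal operculum", "L", "Media orbitofrontal cortex", "L"),
    c("Paracentral lobule", "R", "Precentral gyrus", "L"),
    c("Paracentral lobule", "L", "Rolandic operculum", "L")
  )
  idx <- t(vapply(pairs, function(p)
    c(atlas_roi(atlas, p[1], p[2]), atlas_roi(atlas, p[3], p[4])),
    integer(2)))
  data.frame(roi_i = idx[, 1], roi_j = idx[, 2],
             FESZ = coupling, UHR = coupling, HC = 0)
}

#' Covariate table for a synthetic cohort
#'
#' One row per subject with group label, gender flag (1 = female), age,
#' education and the eight MCCB scores, drawn from group-specific normal
#' distributions truncated to non-negative values.
#'
#' @param config a [synth_config()].
#' @return data.frame (`subject`, `group`, `gender`, `age`, `education`,
#'   `SOPV`, `AVV`, `WMV`, `VBLV`, `VSLV`, `RPSV`, `SCV`, `OCV`).
#' @export
generate_feature_covariates <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cp <- config$covariate_params
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  set.seed(config$seed + 90001L)
  out <- data.frame(subject = sprintf("S%03d", seq_len(n)), group = groups,
                    stringsAsFactors = FALSE)
  out$gender <- rbinom(n, 1L, cp$female_rate[groups])
  for (v in names(cp$mean_sd)) {
    m <- cp$mean_sd[[v]]["mean", groups]
    s <- cp$mean_sd[[v]]["sd", groups]
    out[[v]] <- rnorm_trunc(n, m, s, lower = 0)
  }
  out
}

# truncated-normal draw by rejection; SD 0 collapses to the mean
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad) && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower]
    guard <- guard + 1L
  }
  pmax(x, lower)
}

#' Cohort design: everything but the raw epochs
#'
#' Fixes the shared head model (atlas, calibrated lead field), group labels,
#' per-subject amplitude draws, covariates, per-subject RNG streams and the
#' planted-truth record. Epochs for subject i are then produced on demand by
#' [generate_subject_epochs()], so a full cohort never needs to be held in
#' memory; [generate_cohort()] materializes all epochs for small settings.
#'
#' The lead field is calibrated so that one microvolt of source amplitude in
#' the auditory regions produces one microvolt (after average reference) on
#' the mean of the three vertex-nearest channels, which ties the generator's
#' amplitude parameters to the sensor-level P50 measures.
#'
#' @param config a [synth_config()].
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  atlas <- make_atlas(config$sources_per_roi)
  lf <- make_lead_field(config$n_sensors, atlas, config$lead_field_type)

  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)

  # auditory sources: bilateral superior temporal gyrus centroids
  aud <- c(atlas_roi(atlas, "Superior temporal gyrus", "L"),
           atlas_roi(atlas, "Superior temporal gyrus", "R"))
  aud_src <- atlas$source[atlas$centroid][aud]
  if (lf$type == "spherical") {
    # orient the auditory dipoles toward the vertex-subset response so the
    # calibration below is well conditioned
    for (s in aud_src) {
      d <- sweep(lf$sensor_pos, 2, lf$source_pos[s, ])
      a <- d / (rowSums(d^2)^1.5 * 4 * pi)
      ac <- sweep(a, 2, colMeans(a))
      m <- colMeans(ac[lf$vertex_channels, , drop = FALSE])
      ori <- m / sqrt(sum(m^2))
      lf$orientations[s, ] <- ori
      lf$gain[, s] <- a %*% ori
    }
  }
  gc_gain <- sweep(lf$gain, 2, colMeans(lf$gain))  # average-referenced gain
  geff <- mean(rowSums(gc_gain[lf$vertex_channels, aud_src, drop = FALSE]))
  if (abs(geff) < 1e-12) stop("vertex calibration failed (zero gain)")
  lf$gain <- lf$gain / geff
  lf$calibration <- geff

  amp_draw <- function(tab) {
    m <- tab["mean", groups]; s <- tab["sd", groups]
    rnorm_trunc(n, m, s, lower = 0.05)
  }
  s1_amp <- amp_draw(config$s1_amp_mean_sd)
  s2_amp <- amp_draw(config$s2_amp_mean_sd)

  covariates <- generate_feature_covariates(config)

  structure(list(
    config = config, atlas = atlas, lead_field = lf,
    subjects = covariates$subject, labels = groups,
    subject_seeds = subject_seeds,
    auditory_rois = aud, auditory_sources = aud_src,
    s1_amp = s1_amp, s2_amp = s2_amp,
    covariates = covariates,
    truth = list(planted_edges = config$planted_edges,
                 s1_amp = s1_amp, s2_amp = s2_amp,
                 auditory_rois = aud)
  ), class = "cohort_design")
}

# 1/f (spectral exponent 1) noise, one column per signal, synthesized in
# the frequency domain at a composite length > n (so truncation breaks the
# circular periodicity) and normalized to the requested SD. Columns are
# generated in chunks to bound the transient complex storage.
pink_noise <- function(n, ncols, sd = 1, chunk = 1536L) {
  if (ncols == 0L) return(matrix(0, n, 0L))
  nfft <- next_fast_len(n + min(n, 512L))
  half <- nfft %/% 2L
  f <- seq_len(half - 1L)
  scale <- 1 / sqrt(f)
  out <- matrix(0, n, ncols)
  done <- 0L
  while (done < ncols) {
    b <- min(chunk, ncols - done)
    re <- matrix(rnorm(length(f) * b), length(f), b) * scale
    im <- matrix(rnorm(length(f) * b), length(f), b) * scale
    spec <- matrix(0 + 0i, nfft, b)
    spec[f + 1L, ] <- complex(real = re, imaginary = im)
    spec[nfft - f + 1L, ] <- Conj(spec[f + 1L, ])
    x <- Re(mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE]
    out[, done + seq_len(b)] <- x
    done <- done + b
  }
  out <- sweep(out, 2, colMeans(out))
  s <- sqrt(colMeans(out^2))
  s[s < 1e-15] <- 1
  sweep(out, 2, s, "/") * sd
}

next_fast_len <- function(n) {
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(as.integer(k))
    k <- k + 1
  }
}

# smooth (Hann) window over [from_ms, to_ms] on the epoch time axis
window_taper <- function(times_ms, from_ms, to_ms) {
  w <- numeric(length(times_ms))
  inside <- times_ms >= from_ms & times_ms <= to_ms
  u <- (times_ms[inside] - from_ms) / (to_ms - from_ms)
  w[inside] <- 0.5 - 0.5 * cos(2 * pi * u)
  w
}

#' Generate the epoched sensor data of one subject
#'
#' Builds `n_trials` paired-click epochs: per-source 1/f background noise,
#' Gaussian-windowed P50 bursts in the auditory regions (S1 at +50 ms, S2 at
#' +550 ms with the subject's S2 amplitude), planted-coupling latents in the
#' 30-90 ms post-click windows, projection through the calibrated lead field
#' and spatially white sensor noise.
#'
#' @param design a [cohort_design()].
#' @param i subject index.
#' @return an [epoch_set()].
#' @export
generate_subject_epochs <- function(design, i) {
  stopifnot(inherits(design, "cohort_design"), i >= 1,
            i <= length(design$subjects))
  cfg <- design$config
  set.seed(design$subject_seeds[i])
  fs <- cfg$fs
  times <- seq(cfg$epoch_ms[1], cfg$epoch_ms[2], by = 1000 / fs)
  ns <- length(times)
  nsrc <- cfg$n_sources
  ntr <- cfg$n_trials
  nch <- cfg$n_sensors
  G <- design$lead_field$gain

  burst <- function(peak_ms)
    exp(-(times - peak_ms)^2 / (2 * cfg$burst_sd_ms^2))
  s1_wave <- design$s1_amp[i] * burst(cfg$burst_peak_ms)
  s2_wave <- design$s2_amp[i] * burst(cfg$s2_offset_ms + cfg$burst_peak_ms)
  aud_wave <- s1_wave + s2_wave

  pe <- cfg$planted_edges
  g <- design$labels[i]
  cpl <- NULL
  active <- integer(0)
  if (!is.null(pe) && nrow(pe)) {
    cpl <- pe[[g]]
    active <- which(cpl > 0)
  }
  wins <- rbind(c(30, 90), c(cfg$s2_offset_ms + 30, cfg$s2_offset_ms + 90))
  tapers <- lapply(seq_len(nrow(wins)),
                   function(w) window_taper(times, wins[w, 1], wins[w, 2]))

  aud_src <- design$auditory_sources
  centroid_src <- design$atlas$source[design$atlas$centroid]

  # trial-locked planted activity: one smooth latent waveform per edge and
  # click window, drawn once for this subject, injected into both regions
  # on every trial (only evoked activity survives trial averaging)
  planted <- matrix(0, ns, nsrc)
  if (length(active)) {
    for (w in seq_along(tapers)) {
      taper <- tapers[[w]]
      inside <- taper > 0
      z <- pink_noise(ns, length(active))
      for (k in seq_along(active)) {
        e <- active[k]
        u <- z[, k] * taper
        u <- u / sqrt(mean(u[inside]^2))           # unit RMS in the window
        u <- cpl[e] * cfg$planted_amp_uv * u
        si <- centroid_src[pe$roi_i[e]]
        sj <- centroid_src[pe$roi_j[e]]
        planted[, si] <- planted[, si] + u
        planted[, sj] <- planted[, sj] + u
      }
    }
  }
  planted[, aud_src] <- planted[, aud_src] + aud_wave

  # per-trial background noise for all trials in one batch
  noise <- pink_noise(ns, nsrc * ntr, sd = cfg$noise_sd)

  dat <- array(0, dim = c(ns, nch, ntr))
  tG <- t(G)
  for (tr in seq_len(ntr)) {
    S <- noise[, (tr - 1L) * nsrc + seq_len(nsrc), drop = FALSE] + planted
    X <- S %*% tG                                  # samples x channels
    if (cfg$sensor_noise_sd > 0)
      X <- X + matrix(rnorm(nch * ns, sd = cfg$sensor_noise_sd), ns, nch)
    dat[, , tr] <- X
  }
  data <- aperm(dat, c(3, 2, 1))
  epoch_set(data, fs = fs, times_ms = times,
            s2_offset_ms = cfg$s2_offset_ms,
            channels = design$lead_field$sensor_names,
            subject = design$subjects[i])
}

#' Generate a full synthetic cohort
#'
#' Materializes the design plus every subject's epochs. Intended for small
#' configurations; for full-size cohorts prefer [cohort_design()] +
#' [generate_subject_epochs()] (or [run_pipeline()], which streams subjects).
#'
#' @param config a [synth_config()].
#' @return list of class `synth_cohort`: `design`, `epochs` (list of
#'   [epoch_set()]), plus the design's `atlas`, `lead_field`, `labels`,
#'   `covariates` and `truth` exposed at the top level.
#' @export
generate_cohort <- function(config) {
  design <- cohort_design(config)
  epochs <- lapply(seq_along(design$subjects),
                   function(i) generate_subject_epochs(design, i))
  structure(list(design = design, epochs = epochs, atlas = design$atlas,
                 lead_field = design$lead_field, labels = design$labels,
                 covariates = design$covariates, truth = design$truth),
            class = "synth_cohort")
}
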
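make_epochs <- function(data, fs = 1000) {
  times <- seq(-200, 1000, by = 1000 / fs)
  epoch_set(data, fs = fs, times_ms = times, subject = "T01")
}

test_that("baseline correction zeroes the pre-stimulus mean, offsets included", {
  set.seed(1)
  d <- array(rnorm(4 * 3 * 1201, sd = 2), dim = c(4, 3, 1201))
  d[2, , ] <- d[2, , ] + 57        # constant offset trial
  pp <- preprocess_epochs(make_epochs(d), reject_threshold_uv = 1e6)
  pre <- which(pp$times_ms < 0)
  for (tr in seq_len(dim(pp$data)[1]))
    expect_equal(max(abs(rowMeans(pp$data[tr, , pre]))), 0, tolerance = 1e-9)
})

test_that("average referencing removes the channel mean and is idempotent", {
  set.seed(2)
  d <- array(rnorm(2 * 5 * 1201), dim = c(2, 5, 1201))
  pp <- preprocess_epochs(make_epochs(d), reject_threshold_uv = 1e6)
  for (tr in 1:2)
    expect_lt(max(abs(colMeans(pp$data[tr, , ]))), 1e-9)
  pp2 <- preprocess_epochs(pp, reject_threshold_uv = 1e6)
  # re-referencing (and re-baselining) an already referenced set: channel
  # means stay zero and the data are changed only by the repeated filter
  for (tr in 1:2)
    expect_lt(max(abs(colMeans(pp2$data[tr, , ]))), 1e-9)
})

test_that("trials with large artifacts are rejected; rejecting all is an error", {
  set.seed(3)
  d <- array(rnorm(5 * 4 * 1201, sd = 5), dim = c(5, 4, 1201))
  d[3, 2, 600] <- 500              # injected spike
  pp <- preprocess_epochs(make_epochs(d), reject_threshold_uv = 100)
  expect_equal(dim(pp$data)[1], 4L)
  expect_equal(pp$n_rejected, 1L)
  d2 <- array(rnorm(2 * 4 * 1201, sd = 300), dim = c(2, 4, 1201))
  expect_error(preprocess_epochs(make_epochs(d2), reject_threshold_uv = 10),
               "all trials rejected.*T01")
})

test_that("a 60 Hz interferer is attenuated by at least 20 dB in the 1-40 Hz band", {
  fs <- 1000
  t <- seq(-0.2, 1, by = 1 / fs)
  x <- sin(2 * pi * 60 * t)
  y <- zerophase_bandpass(x, fs, c(1, 40))
  # FFT oracle: power at the 60 Hz bin before and after
  n <- length(t)
  f <- (seq_len(n) - 1) * fs / n
  k <- which.min(abs(f - 60))
  p_in <- abs(fft(x)[k])^2
  p_out <- abs(fft(y)[k])^2
  expect_gt(10 * log10(p_in / p_out), 20)
  # and a mid-band tone passes essentially unchanged
  xm <- sin(2 * pi * 10 * t)
  ym <- zerophase_bandpass(xm, fs, c(1, 40))
  mid <- 200:1000
  expect_equal(sqrt(mean(ym[mid]^2) / mean(xm[mid]^2)), 1, tolerance = 0.01)
})

test_that("frequency-domain filter matches signal::filtfilt's magnitude response", {
  fs <- 1000
  freqs <- c(5, 20, 35, 55, 80)
  bf <- signal::butter(4, c(1, 40) / (fs / 2), type = "pass")
  t <- seq(0, 2, by = 1 / fs)
  for (f0 in freqs) {
    x <- sin(2 * pi * f0 * t)
    y1 <- zerophase_bandpass(x, fs, c(1, 40), order = 4)
    y2 <- signal::filtfilt(bf, x)
    mid <- 500:1500
    g1 <- sqrt(mean(y1[mid]^2) / mean(x[mid]^2))
    g2 <- sqrt(mean(y2[mid]^2) / mean(x[mid]^2))
    expect_lt(abs(g1 - g2), 0.01 + 0.05 * g2)
  }
})

test_that("trial averaging is the arithmetic mean with the expected noise reduction", {
  set.seed(4)
  x <- array(rnorm(1 * 2 * 1201), dim = c(1, 2, 1201))
  sym <- array(0, dim = c(2, 2, 1201))
  sym[1, , ] <- x[1, , ]
  sym[2, , ] <- -x[1, , ]
  expect_equal(average_erp(make_epochs(sym)),
               matrix(0, 2, 1201), ignore_attr = TRUE)
  expect_equal(average_erp(make_epochs(x))[1, ], x[1, 1, ],
               ignore_attr = TRUE)
  # 80 i.i.d. noise trials: mean-waveform SD ~ sigma / sqrt(80)
  sigma <- 3
  d <- array(rnorm(80 * 1 * 1201, sd = sigma), dim = c(80, 1, 1201))
  avg <- average_erp(make_epochs(d))
  expect_equal(sd(avg), sigma / sqrt(80), tolerance = 0.2)
})

test_that("P50 detection is the windowed positive argmax with earliest-tie rule", {
  times <- seq(-200, 1000, by = 1)
  bump <- function(a, mu, s = 5) a * exp(-(times - mu)^2 / (2 * s^2))
  w1 <- matrix(bump(1.0, 60), nrow = 1)
  p <- detect_p50(w1, times, onset_ms = 0)
  expect_equal(p$amplitude, 1.0, tolerance = 1e-6)
  expect_equal(p$latency_ms, 60)
  w2 <- matrix(bump(0.8, 45) + bump(1.2, 70), nrow = 1)
  p2 <- detect_p50(w2, times, onset_ms = 0)
  expect_equal(p2$latency_ms, 70)
  expect_equal(p2$amplitude, 1.2, tolerance = 1e-3)
  z <- matrix(0, 1, length(times))
  pz <- detect_p50(z, times, onset_ms = 0)
  expect_equal(pz$amplitude, 0)
  expect_equal(pz$latency_ms, 30)   # earliest tie
  expect_error(detect_p50(w1, times, onset_ms = 950), "outside")
})

test_that("P50 detector agrees with an exhaustive argmax oracle", {
  set.seed(5)
  times <- seq(-200, 1000, by = 1)
  for (rep in 1:25) {
    tr <- rnorm(length(times))
    onset <- sample(c(0, 500), 1)
    got <- detect_p50(matrix(tr, 1), times, onset_ms = onset)
    want <- oracle_peak(tr, times, onset + 30, onset + 90)
    expect_equal(got$amplitude, want$amplitude)
    expect_equal(got$latency_ms + onset, want$latency)
  }
})

test_that("gating measures implement the difference, ratio and exclusion rules", {
  m <- gating_measures(list(amplitude = 2, latency_ms = 50),
                       list(amplitude = 1, latency_ms = 55))
  expect_equal(m$diff, 1)
  expect_equal(m$ratio, 0.5)
  expect_true(m$valid)
  low <- gating_measures(list(amplitude = 0.4, latency_ms = 50),
                         list(amplitude = 0.2, latency_ms = 55))
  expect_false(low$valid)
  zero <- gating_measures(list(amplitude = 0, latency_ms = 50),
                          list(amplitude = 0.2, latency_ms = 55))
  expect_true(is.na(zero$ratio))
  # published FESZ group means: 1.24 - 0.99 = 0.25
  pub <- gating_measures(list(amplitude = 1.24, latency_ms = 50),
                         list(amplitude = 0.99, latency_ms = 52))
  expect_equal(pub$diff, 0.25)
  expect_true(pub$valid)
})

test_that("condition segments cover 30-90 ms inclusive and subtract pointwise", {
  times <- seq(-200, 1000, by = 1)
  set.seed(6)
  avg <- matrix(rnorm(3 * length(times)), 3)
  seg <- extract_segments(avg, times)
  expect_equal(ncol(seg$S1), 61L)           # 1000 Hz, endpoints inclusive
  expect_equal(ncol(seg$S2), 61L)
  expect_equal(seg$window_ms, 30:90)
  expect_equal(seg$S1_S2, seg$S1 - seg$S2)
  # identical S1/S2 waves: zero gating segment
  per <- avg
  per[, times >= 530 & times <= 590] <- per[, times >= 30 & times <= 90]
  seg2 <- extract_segments(per, times)
  expect_equal(max(abs(seg2$S1_S2)), 0)
  # linearity: s1 = 2 * s2 means the gating segment equals s2
  lin <- avg
  lin[, times >= 30 & times <= 90] <- 2 * lin[, times >= 530 & times <= 590]
  seg3 <- extract_segments(lin, times)
  expect_equal(seg3$S1_S2, seg3$S2)
})
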
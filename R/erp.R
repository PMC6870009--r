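#' Epoched multichannel ERP data for one subject
#'
#' @param data numeric array, trials x channels x samples, in microvolt.
#' @param fs sampling rate (Hz).
#' @param times_ms time axis in ms relative to the S1 click (must cover at
#'   least -200..+1000 ms).
#' @param s2_offset_ms latency of the S2 click after S1 (default 500).
#' @param channels channel names.
#' @param subject subject identifier.
#' @param n_rejected trials dropped by artifact rejection so far.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, times_ms, s2_offset_ms = 500,
                      channels = NULL, subject = NA_character_,
                      n_rejected = 0L) {
  stopifnot(length(dim(data)) == 3, fs > 0,
            length(times_ms) == dim(data)[3])
  if (times_ms[1] > -200 || times_ms[length(times_ms)] < 1000)
    stop("epoch must cover at least -200..+1000 ms around S1 onset")
  t0_idx <- which.min(abs(times_ms))
  if (abs(times_ms[t0_idx]) > 1e-9)
    stop("time axis must contain the S1 onset sample (t = 0)")
  if (is.null(channels)) channels <- sprintf("E%03d", seq_len(dim(data)[2]))
  structure(list(data = data, fs = fs, times_ms = times_ms, t0_idx = t0_idx,
                 s2_offset_ms = s2_offset_ms, channels = channels,
                 subject = subject, n_rejected = as.integer(n_rejected)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set %s: %d trials x %d channels x %d samples @ %g Hz, %d rejected>\n",
              x$subject, d[1], d[2], d[3], x$fs, x$n_rejected))
  invisible(x)
}

# Analytic squared-magnitude (two-pass / zero-phase) Butterworth band-pass
# response at frequencies f for design order `order`.
butter_bandpass_mag2 <- function(f, low, high, order) {
  f0sq <- low * high
  bw <- high - low
  x <- ifelse(f == 0, Inf, (f^2 - f0sq) / (f * bw))
  1 / (1 + x^(2 * order))
}

#' Zero-phase Butterworth band-pass of the columns of a matrix
#'
#' Applies the two-pass (forward-backward) magnitude response of a
#' Butterworth band-pass design of order `order` with exactly zero phase,
#' evaluated in the frequency domain on reflection-padded signals. The
#' magnitude response equals `signal::filtfilt` with `signal::butter(order,
#' band/(fs/2))`; the frequency-domain route vectorizes over many traces.
#'
#' @param x numeric matrix, samples x signals (a vector is treated as one
#'   column).
#' @param fs sampling rate (Hz).
#' @param band `c(low, high)` in Hz, inside (0, fs/2).
#' @param order Butterworth design order (default 4; the applied response is
#'   its zero-phase square).
#' @return filtered matrix of the same shape.
#' @export
zerophase_bandpass <- function(x, fs, band, order = 4) {
  v <- is.null(dim(x))
  if (v) x <- matrix(x, ncol = 1)
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  n <- nrow(x)
  pad <- min(n - 1L, max(64L, ceiling(0.4 * n)))
  nfft <- next_fast_len(n + 2L * pad)
  idx_pre <- pad + 1L - seq_len(pad)          # reflect head
  idx_post <- n - seq_len(pad)                # reflect tail
  xp <- rbind(x[idx_pre, , drop = FALSE], x,
              x[idx_post, , drop = FALSE],
              matrix(0, nfft - n - 2L * pad, ncol(x)))
  f <- c(seq(0, floor(nfft / 2)), seq(-ceiling(nfft / 2) + 1, -1)) * fs / nfft
  h <- butter_bandpass_mag2(abs(f), band[1], band[2], order)
  y <- Re(mvfft(mvfft(xp) * h, inverse = TRUE)) / nfft
  out <- y[pad + seq_len(n), , drop = FALSE]
  if (v) drop(out) else out
}

#' Preprocess raw epochs
#'
#' Per trial: baseline offset removal, artifact rejection by absolute peak
#' amplitude on the raw trace, average re-referencing, zero-phase band-pass
#' filtering, and baseline correction over the pre-stimulus window. The
#' number of rejected trials is recorded on the returned `epoch_set`.
#'
#' @param raw an [epoch_set()].
#' @param band filter band `c(low, high)` in Hz (default 1-40).
#' @param reject_threshold_uv absolute amplitude threshold (microvolt,
#'   default 100) applied to the offset-removed raw trace.
#' @param order filter design order, see [zerophase_bandpass()].
#' @return a preprocessed [epoch_set()].
#' @export
preprocess_epochs <- function(raw, band = c(1, 40),
                              reject_threshold_uv = 100, order = 4) {
  stopifnot(inherits(raw, "epoch_set"),
            band[1] > 0, band[2] < raw$fs / 2)
  d <- dim(raw$data)
  pre <- which(raw$times_ms >= -200 & raw$times_ms < 0)
  # offset-removed raw peaks decide rejection
  keep <- logical(d[1])
  for (tr in seq_len(d[1])) {
    x <- raw$data[tr, , , drop = TRUE]
    x <- x - rowMeans(x[, pre, drop = FALSE])
    keep[tr] <- max(abs(x)) <= reject_threshold_uv
  }
  if (!any(keep))
    stop("all trials rejected for subject ", raw$subject)
  data <- raw$data[keep, , , drop = FALSE]
  nt <- dim(data)[1]; nch <- dim(data)[2]; ns <- dim(data)[3]
  # samples x (channels within trial) working orientation
  m <- matrix(aperm(data, c(3, 2, 1)), ns, nch * nt)
  for (tr in seq_len(nt)) {                        # average reference
    cols <- (tr - 1L) * nch + seq_len(nch)
    m[, cols] <- m[, cols] - rowMeans(m[, cols, drop = FALSE])
  }
  m <- zerophase_bandpass(m, raw$fs, band, order)  # one batched filter pass
  m <- sweep(m, 2, colMeans(m[pre, , drop = FALSE]))   # baseline correction
  data <- aperm(array(m, c(ns, nch, nt)), c(3, 2, 1))
  epoch_set(data, raw$fs, raw$times_ms, raw$s2_offset_ms, raw$channels,
            raw$subject, n_rejected = raw$n_rejected + sum(!keep))
}

#' Trial-average ERP waveform
#'
#' @param epochs an [epoch_set()] with at least one retained trial.
#' @return channels x samples matrix with the time axis attached as
#'   attribute `times_ms`.
#' @export
average_erp <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"), dim(epochs$data)[1] >= 1)
  avg <- colMeans(epochs$data)                    # mean over trials
  attr(avg, "times_ms") <- epochs$times_ms
  avg
}

#' Detect the P50 component in an averaged waveform
#'
#' The P50 is the maximum positive-going sample of the channel-subset mean
#' within 30-90 ms after the click onset (window endpoints inclusive, ties
#' resolved toward the earliest latency).
#'
#' @param waveform channels x samples matrix (or a single-channel vector).
#' @param times_ms time axis in ms relative to S1 onset; taken from the
#'   waveform's `times_ms` attribute when missing.
#' @param onset_ms onset of the click this P50 follows (0 for S1, 500 for
#'   S2).
#' @param channels indices of the channel subset averaged before peak
#'   picking (default: all channels).
#' @param window_ms search window relative to `onset_ms` (default 30-90).
#' @return list with `amplitude` (microvolt) and `latency_ms` (relative to
#'   `onset_ms`).
#' @export
detect_p50 <- function(waveform, times_ms = NULL, onset_ms = 0,
                       channels = NULL, window_ms = c(30, 90)) {
  if (is.null(dim(waveform))) waveform <- matrix(waveform, nrow = 1)
  if (is.null(times_ms)) times_ms <- attr(waveform, "times_ms")
  stopifnot(!is.null(times_ms), length(times_ms) == ncol(waveform))
  if (is.null(channels)) channels <- seq_len(nrow(waveform))
  lo <- onset_ms + window_ms[1]
  hi <- onset_ms + window_ms[2]
  if (times_ms[1] > lo + 1e-9 || times_ms[length(times_ms)] < hi - 1e-9)
    stop("search window ", lo, "-", hi, " ms lies outside the waveform")
  win <- which(times_ms >= lo - 1e-9 & times_ms <= hi + 1e-9)
  tr <- colMeans(waveform[channels, win, drop = FALSE])
  k <- which.max(tr)                       # first index wins on ties
  list(amplitude = tr[[k]], latency_ms = times_ms[win[k]] - onset_ms)
}

#' P50 sensory-gating measures from S1 and S2 peaks
#'
#' Computes the suppression difference (S1-S2) and ratio (S2/S1). Subjects
#' whose S1 amplitude falls below `min_s1_uv` are flagged invalid (the
#' exclusion rule) and are skipped by group statistics but kept in the
#' table; an S1 amplitude of zero leaves the ratio undefined (`NA`).
#'
#' @param s1,s2 lists with `amplitude` and `latency_ms`, as returned by
#'   [detect_p50()].
#' @param min_s1_uv exclusion threshold on the S1 amplitude (microvolt,
#'   default 0.5).
#' @return one-row data.frame (`s1_amp`, `s1_latency`, `s2_amp`,
#'   `s2_latency`, `diff`, `ratio`, `valid`).
#' @export
gating_measures <- function(s1, s2, min_s1_uv = 0.5) {
  stopifnot(is.finite(s1$amplitude), is.finite(s2$amplitude))
  ratio <- if (s1$amplitude > 0) s2$amplitude / s1$amplitude else NA_real_
  data.frame(
    s1_amp = s1$amplitude, s1_latency = s1$latency_ms,
    s2_amp = s2$amplitude, s2_latency = s2$latency_ms,
    diff = s1$amplitude - s2$amplitude,
    ratio = ratio,
    valid = s1$amplitude >= min_s1_uv
  )
}

#' Cut the S1, S2 and gating (S1-S2) analysis segments
#'
#' Extracts the 30-90 ms windows after each click from the averaged
#' waveform (endpoints inclusive; 61 samples at 1000 Hz) and forms the
#' gating segment as the pointwise difference S1 - S2.
#'
#' @param avg channels x samples averaged waveform.
#' @param times_ms time axis (ms, relative to S1); defaults to the
#'   waveform's `times_ms` attribute.
#' @param s2_offset_ms S2 click latency (default 500).
#' @param window_ms window after each onset (default 30-90 ms).
#' @return list of class `condition_segments` with channels x samples
#'   matrices `S1`, `S2`, `S1_S2` and the segment time axis `window_ms`.
#' @export
extract_segments <- function(avg, times_ms = NULL, s2_offset_ms = 500,
                             window_ms = c(30, 90)) {
  if (is.null(times_ms)) times_ms <- attr(avg, "times_ms")
  stopifnot(!is.null(times_ms), length(times_ms) == ncol(avg))
  cut_win <- function(onset) {
    which(times_ms >= onset + window_ms[1] - 1e-9 &
            times_ms <= onset + window_ms[2] + 1e-9)
  }
  i1 <- cut_win(0)
  i2 <- cut_win(s2_offset_ms)
  if (length(i1) != length(i2))
    stop("S1 and S2 windows have different sample counts")
  if (!length(i1)) stop("analysis window lies outside the waveform")
  s1 <- avg[, i1, drop = FALSE]
  s2 <- avg[, i2, drop = FALSE]
  structure(list(S1 = s1, S2 = s2, S1_S2 = s1 - s2,
                 window_ms = times_ms[i1]),
            class = "condition_segments")
}

#' Score one subject's P50 measures from preprocessed epochs
#'
#' Convenience wrapper: average, detect the S1 and S2 P50 on a channel
#' subset, compute gating measures and cut the condition segments.
#'
#' @param epochs preprocessed [epoch_set()].
#' @param channels channel subset for sensor-level P50 scoring (default:
#'   all).
#' @param min_s1_uv exclusion threshold, see [gating_measures()].
#' @return list with `measures` (one-row data.frame), `segments`
#'   ([extract_segments()] output) and `average` (channels x samples).
#' @export
erp_measures <- function(epochs, channels = NULL, min_s1_uv = 0.5) {
  avg <- average_erp(epochs)
  s1 <- detect_p50(avg, epochs$times_ms, 0, channels)
  s2 <- detect_p50(avg, epochs$times_ms, epochs$s2_offset_ms, channels)
  m <- gating_measures(s1, s2, min_s1_uv)
  m <- cbind(data.frame(subject = epochs$subject, stringsAsFactors = FALSE), m)
  list(measures = m,
       segments = extract_segments(avg, epochs$times_ms,
                                   epochs$s2_offset_ms),
       average = avg)
}
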
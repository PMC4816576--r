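#' Band-pass filter specification
#'
#' Linear-phase FIR band-pass (Hamming window design). The default band
#' of 0.5-25 Hz matches standard response-locked ERP preprocessing. The
#' filter is applied with group-delay compensation, so the realized
#' response is zero-phase.
#'
#' @param highpass_hz lower band edge in Hz (default 0.5).
#' @param lowpass_hz upper band edge in Hz (default 25).
#' @param order FIR order (even; `order + 1` taps). The default gives a
#'   transition band of roughly 10 Hz at a 500 Hz sampling rate, ample for
#'   a 20 dB stop at 50 Hz while leaving 10 Hz activity untouched.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_hz = 0.5, lowpass_hz = 25, order = 166) {
  if (!(highpass_hz > 0 && highpass_hz < lowpass_hz))
    stopf("need 0 < highpass < lowpass")
  if (order %% 2 != 0) stopf("order must be even")
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 order = as.integer(order)),
            class = "filter_spec")
}

# FFT-based application of a linear-phase FIR to the columns of a
# samples x series matrix, with reflection padding and group-delay
# compensation (net effect: zero-phase filtering).
apply_fir_matrix <- function(x, h) {
  S <- nrow(x)
  L <- (length(h) - 1) %/% 2
  pad_top <- x[pmin(L + 1, S):2, , drop = FALSE][seq_len(min(L, S - 1)), , drop = FALSE]
  if (nrow(pad_top) < L) pad_top <- rbind(matrix(x[1, ], L - nrow(pad_top), ncol(x), byrow = TRUE), pad_top)
  pad_bot <- x[(S - 1):pmax(S - L, 1), , drop = FALSE][seq_len(min(L, S - 1)), , drop = FALSE]
  if (nrow(pad_bot) < L) pad_bot <- rbind(pad_bot, matrix(x[S, ], L - nrow(pad_bot), ncol(x), byrow = TRUE))
  xp <- rbind(pad_top, x, pad_bot)
  P <- nrow(xp)
  N <- stats::nextn(P + length(h) - 1)
  H <- stats::fft(c(h, rep(0, N - length(h))))
  X <- stats::mvfft(rbind(xp, matrix(0, N - P, ncol(xp))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / N
  y[(2 * L + 1):(2 * L + S), , drop = FALSE]
}

#' Zero-phase FIR band-pass filter of epoched data
#'
#' Filters every trial and channel along time with a linear-phase FIR
#' band-pass, compensating the filter's group delay so the output is
#' zero-phase. Metadata are unchanged.
#'
#' @param x an `erp_epochs`.
#' @param spec a `filter_spec`.
#' @return filtered `erp_epochs`.
#' @export
bandpass_filter <- function(x, spec = filter_spec()) {
  fs <- x$sampling_rate
  if (spec$lowpass_hz >= fs / 2) stopf("lowpass must be below Nyquist (%g Hz)", fs / 2)
  h <- as.numeric(signal::fir1(spec$order,
                               c(spec$highpass_hz, spec$lowpass_hz) / (fs / 2),
                               type = "pass"))
  d <- x$data
  n <- dim(d)[1]; C <- dim(d)[2]; S <- dim(d)[3]
  m <- matrix(aperm(d, c(3, 1, 2)), S, n * C)
  y <- apply_fir_matrix(m, h)
  x$data <- aperm(array(y, c(S, n, C)), c(2, 3, 1))
  x
}

#' Frequency response of a filter specification
#'
#' Amplitude response of the realized (zero-phase) filter at the requested
#' frequencies, for a given sampling rate.
#'
#' @param spec a `filter_spec`.
#' @param freqs_hz frequencies at which to evaluate.
#' @param sampling_rate sampling rate in Hz.
#' @return numeric vector of linear gains.
#' @export
filter_gain <- function(spec, freqs_hz, sampling_rate) {
  h <- as.numeric(signal::fir1(spec$order,
                               c(spec$highpass_hz, spec$lowpass_hz) / (sampling_rate / 2),
                               type = "pass"))
  k <- seq_along(h) - 1
  vapply(freqs_hz, function(f) {
    Mod(sum(h * exp(-2i * pi * f / sampling_rate * k)))
  }, numeric(1))
}

#' Re-reference to linked mastoids
#'
#' Subtracts the average of the two mastoid channels from every channel at
#' every sample of every trial.
#'
#' @param x an `erp_epochs`.
#' @param mastoid_channels pair of channel labels (default `c("M1", "M2")`).
#' @return re-referenced `erp_epochs`.
#' @export
rereference_linked_mastoids <- function(x, mastoid_channels = c("M1", "M2")) {
  idx <- match(mastoid_channels, x$montage$channel_names)
  if (anyNA(idx))
    stopf("mastoid channel(s) missing: %s",
          paste(mastoid_channels[is.na(idx)], collapse = ", "))
  ref <- (x$data[, idx[1], , drop = FALSE] + x$data[, idx[2], , drop = FALSE]) / 2
  dim(ref) <- dim(x$data)[c(1, 3)]
  C <- dim(x$data)[2]
  x$data <- x$data - aperm(array(ref, c(dim(ref), C)), c(1, 3, 2))
  x
}

#' Continuous multi-channel recording
#'
#' @param data channel x sample matrix (microvolts).
#' @param montage an `erp_montage` matching the rows of `data`.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `erp_continuous`.
#' @export
continuous_record <- function(data, montage, sampling_rate) {
  if (nrow(data) != length(montage$channel_names))
    stopf("data rows must match montage channels")
  structure(list(data = data, montage = montage, sampling_rate = sampling_rate),
            class = "erp_continuous")
}

#' Segment a continuous recording into epochs
#'
#' Cuts one epoch per event. Events whose window would extend beyond the
#' recording are dropped with a warning. Each epoch is an exact slice of
#' the continuous record (no interpolation or baseline correction).
#'
#' @param continuous an `erp_continuous`.
#' @param events data.frame with a `sample` column (1-based lock sample)
#'   plus per-trial metadata columns (must include `response`).
#' @param window `c(start, end)` in ms relative to the lock event.
#' @param lock `"response"` or `"stimulus"`.
#' @return an `erp_epochs`.
#' @export
segment_epochs <- function(continuous, events, window, lock = "response") {
  fs <- continuous$sampling_rate
  i0 <- round(window[1] * fs / 1000)
  S <- round((window[2] - window[1]) * fs / 1000) + 1
  times <- window[1] + (seq_len(S) - 1) * 1000 / fs
  total <- ncol(continuous$data)
  first <- events$sample + i0
  ok <- first >= 1 & (first + S - 1) <= total
  if (any(!ok))
    warning(sprintf("dropping %d event(s) too close to the recording edge", sum(!ok)))
  events <- events[ok, , drop = FALSE]
  n <- nrow(events)
  C <- nrow(continuous$data)
  out <- array(0, c(n, C, S))
  for (i in seq_len(n)) {
    out[i, , ] <- continuous$data[, (events$sample[i] + i0) + (seq_len(S) - 1)]
  }
  meta <- events[, setdiff(names(events), "sample"), drop = FALSE]
  rownames(meta) <- NULL
  epochs(out, continuous$montage, fs, times, meta, lock = lock)
}

#' Artifact rejection configuration
#'
#' @param z_criterion outlier criterion in pooled standard deviations
#'   (default 3).
#' @param max_reject_fraction maximum fraction of trials that may be
#'   removed (default 0.05).
#' @return an object of class `rejection_config`.
#' @export
rejection_config <- function(z_criterion = 3, max_reject_fraction = 0.05) {
  if (z_criterion <= 0) stopf("z_criterion must be > 0")
  if (max_reject_fraction < 0 || max_reject_fraction > 1)
    stopf("max_reject_fraction must be in [0, 1]")
  structure(list(z_criterion = z_criterion,
                 max_reject_fraction = max_reject_fraction),
            class = "rejection_config")
}

#' Statistical artifact rejection
#'
#' Pools all data points of all trials, EEG channels and samples into one
#' empirical distribution and flags trials containing any point beyond
#' `z_criterion` standard deviations from the pooled mean. At most
#' `floor(max_reject_fraction * n_trials)` trials are removed; if more are
#' flagged, the trials with the largest within-trial maximum |z| are
#' removed first (ties broken by lower trial index). Degenerate input with
#' zero pooled SD rejects nothing. Channels typed `"mastoid"`/`"eog"` in
#' the montage are excluded from the pooled statistics.
#'
#' @param x an `erp_epochs` with at least 2 trials.
#' @param cfg a `rejection_config`.
#' @return list with elements `epochs` (survivors) and `rejected` (integer
#'   indices of removed trials, possibly empty).
#' @export
reject_artifact_trials <- function(x, cfg = rejection_config()) {
  n <- n_trials(x)
  if (n < 2) stopf("need at least 2 trials")
  keep_ch <- which(x$montage$channel_types == "eeg")
  if (length(keep_ch) == 0) keep_ch <- seq_along(x$montage$channel_names)
  d <- x$data[, keep_ch, , drop = FALSE]
  mu <- mean(d)
  sdev <- stats::sd(as.vector(d))
  cap <- floor(cfg$max_reject_fraction * n)
  if (!is.finite(sdev) || sdev == 0 || cap == 0)
    return(list(epochs = x, rejected = integer(0)))
  zmax <- apply(abs(d - mu), 1, max) / sdev
  flagged <- which(zmax > cfg$z_criterion)
  if (length(flagged) > cap) {
    ord <- flagged[order(-zmax[flagged], flagged)]
    rejected <- sort(ord[seq_len(cap)])
  } else {
    rejected <- flagged
  }
  if (length(rejected) == 0) return(list(epochs = x, rejected = integer(0)))
  list(epochs = subset_trials(x, -rejected), rejected = rejected)
}

#' Default preprocessing chain
#'
#' Band-pass filter, optional linked-mastoid re-reference (skipped when
#' the montage lacks mastoids), an identity hook where an external ocular
#' cleaner (e.g. an ICA-based one) may be plugged in, and statistical
#' artifact rejection.
#'
#' @param x an `erp_epochs`.
#' @param filter a `filter_spec`, or `NULL` to skip filtering.
#' @param rejection a `rejection_config`, or `NULL` to skip rejection.
#' @param rereference logical; re-reference to linked mastoids if present.
#' @param ocular_hook function taking and returning an `erp_epochs`;
#'   defaults to the identity.
#' @return list with `epochs` and `rejected` (as in
#'   [reject_artifact_trials()]).
#' @export
preprocess_epochs <- function(x, filter = filter_spec(),
                              rejection = rejection_config(),
                              rereference = TRUE,
                              ocular_hook = identity) {
  if (!is.null(filter)) x <- bandpass_filter(x, filter)
  if (rereference && all(c("M1", "M2") %in% x$montage$channel_names))
    x <- rereference_linked_mastoids(x)
  x <- ocular_hook(x)
  if (is.null(rejection)) return(list(epochs = x, rejected = integer(0)))
  reject_artifact_trials(x, rejection)
}
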
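# Online closed-loop SMR pipeline: large-Laplacian spatial filter, zero-phase
# Butterworth band-pass + notch, 1-s Hanning short-time spectra at a 100-ms
# cadence, within-trial ERSP normalization, FOI calibration, 10-sample
# smoothing and percentile-to-frame mapping.

#' Large-Laplacian spatial filter
#'
#' Subtracts the mean of the next-nearest-neighbor electrodes from the center
#' electrode, sample-wise.
#'
#' @param recording An `eeg_recording` (or any list with `signal` matrix and
#'   `channel_labels`).
#' @param center Center channel label (default `"C3"`).
#' @param neighbors Neighbor channel labels.
#' @return Numeric vector: the spatially filtered single-channel signal.
#' @export
large_laplacian <- function(recording, center = "C3",
                            neighbors = c("F3", "P3", "T7", "Cz")) {
  labs <- recording$channel_labels
  missing <- setdiff(c(center, neighbors), labs)
  if (length(missing) > 0) {
    stop("channel(s) not in recording: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  center_sig <- recording$signal[center, ]
  nb <- recording$signal[neighbors, , drop = FALSE]
  as.numeric(center_sig - colMeans(nb))
}

#' Zero-phase band-pass and notch filtering of a signal buffer
#'
#' Third-order Butterworth band-pass (default 3-70 Hz) and band-stop notch
#' (default 50 Hz), each applied forward and backward (zero phase).
#'
#' @param buffer Numeric vector (one buffer of the spatially filtered signal).
#' @param sampling_rate Hz.
#' @param band Band-pass edges in Hz.
#' @param notch Notch center frequency in Hz (`NULL` to skip).
#' @param notch_halfwidth Half-width of the notch stop band in Hz.
#' @param order Butterworth order.
#' @return Filtered buffer, same length as input.
#' @export
buffer_filter <- function(buffer, sampling_rate, band = c(3, 70),
                          notch = 50, notch_halfwidth = 2, order = 3) {
  nyq <- sampling_rate / 2
  if (length(buffer) < 3 * (2 * order + 1)) {
    stop("buffer too short for stable forward-backward filtering", call. = FALSE)
  }
  bp <- signal::butter(order, band / nyq, type = "pass")
  out <- signal::filtfilt(bp, buffer)
  if (!is.null(notch)) {
    bs <- signal::butter(order, (notch + c(-1, 1) * notch_halfwidth) / nyq,
                         type = "stop")
    out <- signal::filtfilt(bs, out)
  }
  out
}

#' Hanning-windowed short-time spectral power of the latest 1-s window
#'
#' Computes the one-sided Hanning periodogram of the final `window_s` seconds
#' of a buffer. With a 1-s window the bins fall on integer frequencies
#' (1 Hz resolution).
#'
#' @param buffer Filtered signal buffer; its tail is analyzed.
#' @param sampling_rate Hz.
#' @param window_s Analysis window length in seconds.
#' @return List with `freq` (Hz) and `power` (uV^2/Hz per bin), class
#'   `power_sample`.
#' @export
stft_power <- function(buffer, sampling_rate, window_s = 1) {
  n <- round(window_s * sampling_rate)
  if (length(buffer) < n) {
    stop("buffer shorter than the analysis window", call. = FALSE)
  }
  x <- utils::tail(buffer, n)
  w <- hann_window(n)
  X <- stats::fft(x * w)
  k <- seq_len(floor(n / 2))                 # bins 1 .. Nyquist-1
  power <- 2 * Mod(X[k + 1])^2 / (sampling_rate * sum(w^2))
  structure(list(freq = k / window_s, power = power), class = "power_sample")
}

# Vectorized variant: spectra for many windows of one signal at once.
# `ends` are 1-based sample indices of window end points.
stft_power_matrix <- function(x, sampling_rate, ends, window_s = 1) {
  n <- round(window_s * sampling_rate)
  w <- hann_window(n)
  idx <- outer(seq_len(n) - n, ends, "+")    # n x n_windows
  seg <- matrix(x[idx], nrow = n) * w
  X <- stats::mvfft(seg)
  k <- seq_len(floor(n / 2))
  pw <- 2 * Mod(X[k + 1, , drop = FALSE])^2 / (sampling_rate * sum(w^2))
  list(freq = k / window_s, power = pw)      # bins x windows
}

#' Reference spectrum from rest-period power samples
#'
#' Per-bin arithmetic mean of the power samples recorded during the trial's
#' rest period. The reference is recomputed per trial (within-trial
#' normalization).
#'
#' @param power_samples List of `power_sample` objects, or a bins x samples
#'   matrix.
#' @return Numeric vector: per-bin mean power.
#' @export
compute_reference <- function(power_samples) {
  if (is.matrix(power_samples)) {
    if (ncol(power_samples) == 0) stop("empty rest period", call. = FALSE)
    return(rowMeans(power_samples))
  }
  if (length(power_samples) == 0) stop("empty rest period", call. = FALSE)
  rowMeans(vapply(power_samples, function(p) p$power,
                  numeric(length(power_samples[[1]]$power))))
}

#' Event-related spectral perturbation (percent change from reference)
#'
#' `ERSP(f, t) = 100 * (Power(f, t) - Reference(f)) / Reference(f)`.
#'
#' @param power Per-bin power at one time point.
#' @param reference Per-bin rest-period reference (same bins).
#' @return Per-bin ERSP in percent; bounded below by -100.
#' @export
ersp <- function(power, reference) {
  if (inherits(power, "power_sample")) power <- power$power
  if (length(power) != length(reference)) {
    stop("power and reference must share frequency bins", call. = FALSE)
  }
  if (any(reference <= 0)) {
    stop("reference power must be positive in every bin (degenerate calibration)",
         call. = FALSE)
  }
  100 * (power - reference) / reference
}

#' Scalar SMR value from per-bin ERSP
#'
#' Before FOI calibration the SMR is the mean ERSP across the alpha band
#' (8-13 Hz); after calibration it is the ERSP at the frequency of interest.
#'
#' @param ersp_bins Per-bin ERSP values.
#' @param freq Frequencies (Hz) of the bins.
#' @param mode `"band"` (alpha-band mean) or `"foi"` (single calibrated bin).
#' @param foi Frequency of interest in Hz (required for `mode = "foi"`).
#' @param band Alpha band edges, Hz (inclusive).
#' @return Scalar SMR in percent ERSP units.
#' @export
smr_alpha <- function(ersp_bins, freq, mode = c("band", "foi"), foi = NULL,
                      band = c(8, 13)) {
  mode <- match.arg(mode)
  if (mode == "foi") {
    if (is.null(foi)) stop("FOI mode requires a calibrated foi", call. = FALSE)
    i <- which(freq == foi)
    if (length(i) != 1) stop("foi is not a frequency bin", call. = FALSE)
    return(ersp_bins[i])
  }
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) stop("no bins inside the alpha band", call. = FALSE)
  mean(ersp_bins[sel])
}

#' Calibrate the frequency of interest from open-loop ERSP maps
#'
#' The FOI is the alpha-band bin with the most prominent negative
#' (trial-averaged, task-period-averaged) ERSP. Ties break to the lowest
#' frequency; if no bin is negative a warning is emitted and the argmin is
#' returned anyway.
#'
#' @param map An `ersp_map` (see [ersp_timefreq_map()]).
#' @param task_window Trial-relative time window (s) whose 1-s analysis
#'   windows lie entirely within the task period.
#' @param band Alpha band edges in Hz.
#' @return FOI in Hz.
#' @export
calibrate_foi <- function(map, task_window = c(7, 12), band = c(8, 13)) {
  sel_f <- map$freq >= band[1] & map$freq <= band[2]
  sel_t <- map$time >= task_window[1] & map$time <= task_window[2]
  if (!any(sel_f) || !any(sel_t)) {
    stop("map does not cover the alpha band / task window", call. = FALSE)
  }
  prof <- rowMeans(map$ersp[sel_f, sel_t, drop = FALSE])
  if (min(prof) >= 0) {
    warning("no negative task-period ERSP in the alpha band; returning argmin")
  }
  map$freq[sel_f][which.min(prof)]
}

#' Smooth the SMR history
#'
#' Mean of the most recent `min(n, available)` raw SMR values.
#'
#' @param raw_history Numeric vector of raw SMR values, oldest first.
#' @param n Smoothing length (number of most recent samples).
#' @return Smoothed SMR value.
#' @export
smooth_smr <- function(raw_history, n = 10) {
  if (length(raw_history) == 0) stop("empty SMR history", call. = FALSE)
  mean(utils::tail(raw_history, n))
}

#' Feedback calibration object
#'
#' @param foi Frequency of interest, Hz.
#' @param p25,p75 25th and 75th percentiles of the open-loop SMR
#'   distribution, percent ERSP units. Stronger SMR (more negative ERSP,
#'   deeper desynchronization) maps to more abducted finger frames.
#' @param n_frames Number of feedback video frames.
#' @return List of class `feedback_calibration`.
#' @export
feedback_calibration <- function(foi, p25, p75, n_frames = 20) {
  if (p25 > p75) stop("p25 must not exceed p75", call. = FALSE)
  structure(list(foi = foi, p25 = p25, p75 = p75, n_frames = n_frames),
            class = "feedback_calibration")
}

#' Calibrate percentile anchors from an open-loop feedback trace
#'
#' @param smr Vector of smoothed SMR values from the open-loop block.
#' @param foi Calibrated frequency of interest, Hz.
#' @param n_frames Number of feedback frames.
#' @return A [feedback_calibration()].
#' @export
calibrate_percentiles <- function(smr, foi, n_frames = 20) {
  q <- stats::quantile(smr, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  feedback_calibration(foi, q[1], q[2], n_frames)
}

#' Map a smoothed SMR value to a feedback frame index
#'
#' Affine map anchored at the calibration percentiles: SMR at or below the
#' 25th percentile (deepest desynchronization) shows the fully abducted
#' finger (frame `n_frames`), SMR at or above the 75th percentile shows
#' frame 1; values in between are interpolated linearly and rounded
#' (half-up by default), then clipped to `[1, n_frames]`.
#'
#' @param smr Smoothed SMR value (percent ERSP).
#' @param calibration A [feedback_calibration()].
#' @param rounding `"half-up"` or `"nearest"` (banker's rounding).
#' @return Integer frame index in `[1, n_frames]`.
#' @export
map_to_frame <- function(smr, calibration, rounding = c("half-up", "nearest")) {
  rounding <- match.arg(rounding)
  p25 <- calibration$p25; p75 <- calibration$p75
  if (p25 == p75) stop("degenerate calibration: p25 == p75", call. = FALSE)
  frac <- (p75 - smr) / (p75 - p25)          # 1 at p25, 0 at p75
  raw <- 1 + frac * (calibration$n_frames - 1)
  fr <- if (rounding == "half-up") floor(raw + 0.5) else round(raw)
  as.integer(clamp(fr, 1, calibration$n_frames))
}

#' Causal replay of the closed-loop feedback computation
#'
#' Replays the online chain on a recorded session: every `tick_s` seconds the
#' latest `buffer_s` seconds of the Laplacian-filtered signal are band-pass
#' and notch filtered (zero phase), the final 1 s is Fourier transformed with
#' a Hanning window, and the ERSP relative to the current trial's rest-period
#' reference is reduced to a scalar SMR, smoothed over the last `smooth_n`
#' raw values, and mapped to a frame index. Each tick uses only samples up to
#' the tick time, and the rest reference accumulates causally within the
#' trial, so truncating the recording does not alter earlier trace values.
#'
#' Ticks before `buffer_s` seconds of data, and ticks in a trial before the
#' first full rest window, have no SMR value (`NA`).
#'
#' @param recording An `eeg_recording` with events.
#' @param calibration A [feedback_calibration()], or `NULL` for the open-loop
#'   (pre-calibration) mode: SMR is then the alpha-band mean and no frame is
#'   produced.
#' @param center,neighbors Laplacian montage.
#' @param tick_s Update cadence, s.
#' @param buffer_s Buffer length, s.
#' @param window_s Spectral window length, s.
#' @param smooth_n Smoothing length, samples.
#' @param mode `"foi"` or `"band"` SMR mode (FOI-bin when calibrated).
#' @param ... Passed to [buffer_filter()].
#' @return Data frame of class `feedback_trace`: `tick_s`, `trial`,
#'   `raw_smr`, `smoothed_smr`, `frame`.
#' @export
run_closed_loop_replay <- function(recording, calibration = NULL,
                                   center = "C3",
                                   neighbors = c("F3", "P3", "T7", "Cz"),
                                   tick_s = 0.1, buffer_s = 5, window_s = 1,
                                   smooth_n = 10,
                                   mode = if (is.null(calibration)) "band" else "foi",
                                   ...) {
  fs <- recording$sampling_rate
  lap <- large_laplacian(recording, center, neighbors)
  n <- length(lap)
  if (n < buffer_s * fs) stop("recording shorter than one buffer", call. = FALSE)
  if (mode == "foi" && is.null(calibration)) {
    stop("FOI mode requires a calibration", call. = FALSE)
  }

  ev <- recording$events
  rest_on <- ev$onset_sample[ev$label == "rest"]
  if (length(rest_on) == 0) stop("recording has no rest events", call. = FALSE)
  tick_n <- round(tick_s * fs)
  win_n <- round(window_s * fs)
  ticks <- seq(round(buffer_s * fs), n, by = tick_n)

  out <- data.frame(tick_s = ticks / fs, trial = NA_integer_,
                    raw_smr = NA_real_, smoothed_smr = NA_real_,
                    frame = NA_integer_)
  raw_hist <- numeric(0)
  ref_sum <- NULL; ref_n <- 0L; cur_trial <- 0L

  for (i in seq_along(ticks)) {
    tk <- ticks[i]
    trial <- findInterval(tk, rest_on)
    if (trial == 0) next
    out$trial[i] <- trial
    if (trial != cur_trial) {                # new trial: reset the reference
      cur_trial <- trial; ref_sum <- NULL; ref_n <- 0L
    }
    buf <- lap[(tk - buffer_s * fs + 1):tk]
    filt <- buffer_filter(buf, fs, ...)
    pw <- stft_power(filt, fs, window_s)

    # rest tick: the 1-s window lies entirely inside this trial's rest period
    t0 <- rest_on[trial]
    ready_after <- ev$onset_sample[ev$label == "ready" & ev$onset_sample > t0]
    rest_end <- if (length(ready_after)) min(ready_after) - 1L else n
    if ((tk - win_n + 1) >= t0 && tk <= rest_end) {
      ref_sum <- if (is.null(ref_sum)) pw$power else ref_sum + pw$power
      ref_n <- ref_n + 1L
    }
    if (ref_n == 0L) next                    # no reference yet in this trial
    e <- ersp(pw, ref_sum / ref_n)
    raw <- smr_alpha(e, pw$freq, mode = mode,
                     foi = if (mode == "foi") calibration$foi else NULL)
    raw_hist <- c(raw_hist, raw)
    sm <- smooth_smr(raw_hist, smooth_n)
    out$raw_smr[i] <- raw
    out$smoothed_smr[i] <- sm
    if (!is.null(calibration)) out$frame[i] <- map_to_frame(sm, calibration)
  }
  class(out) <- c("feedback_trace", "data.frame")
  out
}
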
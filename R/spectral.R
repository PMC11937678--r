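# Offline spectral analysis: Welch PSD, simplified parameterization of the
# spectrum into an aperiodic 1/f component plus periodic Gaussian peaks,
# individual-alpha-frequency extraction, and trial-averaged time-frequency
# ERSP maps.

#' Welch power spectral density estimate
#'
#' Averaged Hanning-windowed periodograms over overlapping segments, with
#' density scaling (integrating the PSD over frequency recovers the signal
#' variance, Parseval).
#'
#' @param x Numeric signal vector.
#' @param sampling_rate Hz.
#' @param segment_s Segment length in seconds.
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return List of class `psd` with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, sampling_rate, segment_s = 1, overlap = 0.5) {
  n <- round(segment_s * sampling_rate)
  if (length(x) < n) stop("signal shorter than one segment", call. = FALSE)
  step <- max(1L, round(n * (1 - overlap)))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  w <- hann_window(n)
  scale <- sampling_rate * sum(w^2)
  k <- seq_len(floor(n / 2))
  acc <- numeric(length(k))
  for (s in starts) {
    seg <- x[s:(s + n - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    acc <- acc + 2 * Mod(X[k + 1])^2 / scale
  }
  structure(list(freq = k / segment_s, psd = acc / length(starts)),
            class = "psd")
}

# Sum of Gaussian peaks in log10-power space. `par` = c(cf1, h1, sd1, ...).
gaussian_peaks <- function(freq, par) {
  out <- numeric(length(freq))
  if (length(par) == 0) return(out)
  for (i in seq_len(length(par) / 3)) {
    p <- par[(3 * i - 3) + 1:3]
    out <- out + p[2] * exp(-(freq - p[1])^2 / (2 * p[3]^2))
  }
  out
}

# Drop the shorter of two overlapping peaks (centers closer than
# `thresh` times their summed Gaussian SDs), tallest-first.
drop_overlapping_peaks <- function(peaks, thresh = 0.75) {
  if (nrow(peaks) < 2) return(peaks)
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (abs(peaks$cf[i] - peaks$cf[j]) <
          thresh * (peaks$sd[i] + peaks$sd[j])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  peaks[keep, , drop = FALSE]
}

# Joint Levenberg-Marquardt refinement of all peak parameters against the
# flattened (aperiodic-removed) log spectrum.
fit_peaks <- function(freq, flat, guesses, bw_lims) {
  if (nrow(guesses) == 0) return(guesses)
  par0 <- as.numeric(t(guesses[, c("cf", "height", "sd")]))
  lower <- as.numeric(t(cbind(guesses$cf - 2 * guesses$sd, 0, bw_lims[1] / 2)))
  upper <- as.numeric(t(cbind(guesses$cf + 2 * guesses$sd, Inf, bw_lims[2] / 2)))
  fit <- try(minpack.lm::nls.lm(
    par = par0,
    lower = lower, upper = upper,
    fn = function(p) flat - gaussian_peaks(freq, p),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) return(guesses)
  p <- fit$par
  data.frame(cf = p[seq(1, length(p), 3)],
             height = p[seq(2, length(p), 3)],
             sd = p[seq(3, length(p), 3)])
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Simplified spectral parameterization: the log10 PSD is modeled as
#' `offset - exponent * log10(f)` plus a sum of Gaussian peaks. The aperiodic
#' component is first fit robustly (down-weighting peak regions), peaks are
#' extracted iteratively from the flattened spectrum and refined jointly,
#' and the aperiodic fit is then recomputed on the peak-subtracted spectrum.
#'
#' @param psd A `psd` object (see [welch_psd()]), or a list with `freq`
#'   and `psd`.
#' @param fit_range Frequency range (Hz) used for fitting; must exclude 0.
#' @param max_peaks Maximum number of peaks extracted.
#' @param min_peak_height Minimum peak height (log10 power units) to keep.
#' @param peak_threshold Relative detection threshold in SDs of the
#'   flattened-spectrum residual.
#' @param bw_lims Bounds on peak bandwidth (2 SD of the Gaussian), Hz.
#' @return List of class `spectral_params`: `offset`, `exponent`, `peaks`
#'   (data frame `cf`, `height`, `bw`), `fit_range`, `r_squared`, plus the
#'   fitted model curve (`freq`, `model` in log10 power).
#' @export
parameterize_spectrum <- function(psd, fit_range = c(2, 40), max_peaks = 6,
                                  min_peak_height = 0.1, peak_threshold = 2,
                                  bw_lims = c(0.5, 8)) {
  sel <- psd$freq >= fit_range[1] & psd$freq <= fit_range[2]
  freq <- psd$freq[sel]
  pw <- psd$psd[sel]
  if (length(freq) < 6) stop("fit range covers too few frequency bins", call. = FALSE)
  if (any(pw <= 0)) stop("non-positive power inside the fit range", call. = FALSE)
  logp <- log10(pw)
  logf <- log10(freq)

  ap_fit_lm <- function(y, keep = rep(TRUE, length(y))) {
    co <- stats::coef(stats::lm(y[keep] ~ logf[keep]))
    c(offset = unname(co[1]), exponent = unname(-co[2]))
  }
  ap_curve <- function(ap) ap[["offset"]] - ap[["exponent"]] * logf

  # Robust initial aperiodic fit: refit on the half of the points lying
  # lowest above the first fit, so narrow-band peaks do not pull the slope.
  ap <- ap_fit_lm(logp)
  resid0 <- logp - ap_curve(ap)
  ap <- ap_fit_lm(logp, keep = resid0 <= stats::median(resid0))
  flat <- logp - ap_curve(ap)

  # Iterative peak extraction from the flattened spectrum
  guesses <- data.frame(cf = numeric(0), height = numeric(0), sd = numeric(0))
  work <- flat
  for (i in seq_len(max_peaks)) {
    imax <- which.max(work)
    h <- work[imax]
    if (h < max(min_peak_height, peak_threshold * stats::sd(work))) break
    # bandwidth guess from half-height crossings
    above <- work >= h / 2
    lo <- imax; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- imax; while (hi < length(work) && above[hi + 1]) hi <- hi + 1
    fwhm <- max(freq[hi] - freq[lo], diff(freq)[1])
    sd_g <- clamp(fwhm / (2 * sqrt(2 * log(2))), bw_lims[1] / 2, bw_lims[2] / 2)
    guesses <- rbind(guesses, data.frame(cf = freq[imax], height = h, sd = sd_g))
    work <- work - h * exp(-(freq - freq[imax])^2 / (2 * sd_g^2))
  }

  peaks <- fit_peaks(freq, flat, guesses, bw_lims)
  dropped <- drop_overlapping_peaks(peaks)
  if (nrow(dropped) < nrow(peaks)) peaks <- fit_peaks(freq, flat, dropped, bw_lims)

  # Refit the aperiodic component on the peak-subtracted spectrum, masking
  # out the peak neighborhoods so line-shape mismatch cannot tilt the slope;
  # then refine the peaks once against the final flattened spectrum.
  peak_model <- gaussian_peaks(freq, as.numeric(t(peaks[, c("cf", "height", "sd")])))
  outside <- rep(TRUE, length(freq))
  for (i in seq_len(nrow(peaks))) {
    outside <- outside & abs(freq - peaks$cf[i]) > min(2 * 2 * peaks$sd[i], 4)
  }
  if (sum(outside) < 10) outside <- rep(TRUE, length(freq))
  ap <- ap_fit_lm(logp - peak_model, keep = outside)
  flat_final <- logp - ap_curve(ap)
  peaks <- fit_peaks(freq, flat_final, peaks, bw_lims)
  dropped <- drop_overlapping_peaks(peaks)
  if (nrow(dropped) < nrow(peaks)) peaks <- fit_peaks(freq, flat_final, dropped, bw_lims)
  peaks <- peaks[peaks$height >= min_peak_height, , drop = FALSE]
  peaks <- peaks[order(-peaks$height), , drop = FALSE]

  model <- ap_curve(ap) +
    gaussian_peaks(freq, as.numeric(t(peaks[, c("cf", "height", "sd")])))
  r2 <- 1 - sum((logp - model)^2) / max(sum((logp - mean(logp))^2), .Machine$double.eps)
  if (ap[["exponent"]] < 0) {
    warning("negative aperiodic exponent: spectrum rises with frequency")
  }

  structure(list(
    offset = ap[["offset"]], exponent = ap[["exponent"]],
    peaks = data.frame(cf = peaks$cf, height = peaks$height, bw = 2 * peaks$sd),
    fit_range = fit_range, r_squared = r2, freq = freq, model = model
  ), class = "spectral_params")
}

#' Individual alpha frequency from parameterized spectrum
#'
#' Center frequency of the highest peak inside the alpha band. Returns
#' `NA_real_` (the explicit no-IAF outcome) when no alpha peak was found;
#' callers decide the fallback.
#'
#' @param params A `spectral_params` object.
#' @param band Alpha band edges, Hz.
#' @return IAF in Hz, or `NA_real_`.
#' @export
find_iaf <- function(params, band = c(8, 13)) {
  pk <- params$peaks
  pk <- pk[pk$cf >= band[1] & pk$cf <= band[2], , drop = FALSE]
  if (nrow(pk) == 0) return(NA_real_)
  pk$cf[which.max(pk$height)]
}

#' Modeled peak height above the aperiodic fit at the IAF
#'
#' @param params A `spectral_params` object.
#' @param band Alpha band edges, Hz.
#' @return Peak height in log10 power units.
#' @export
peak_height_at_iaf <- function(params, band = c(8, 13)) {
  iaf <- find_iaf(params, band)
  if (is.na(iaf)) stop("no alpha peak: IAF undefined", call. = FALSE)
  pk <- params$peaks
  pk$height[pk$cf == iaf][1]
}

#' Trial-averaged time-frequency ERSP map
#'
#' Offline counterpart of the online chain: the Laplacian trace is band-pass
#' and notch filtered (zero phase, whole recording at once), 1-s Hanning
#' spectra are computed every `tick_s` seconds through each trial, each trial
#' is normalized to its own rest-period reference
#' (`100 * (P - ref) / ref`), and trials are averaged.
#'
#' @param recording An `eeg_recording`, or a numeric vector (already
#'   spatially filtered / source-level series) in which case `events` and
#'   `sampling_rate` must be supplied.
#' @param events Event table (`onset_sample`, `label`) when `recording` is a
#'   plain vector.
#' @param sampling_rate Hz, when `recording` is a plain vector.
#' @param center,neighbors Laplacian montage for `eeg_recording` input.
#' @param freq_range Frequency range (Hz) retained in the map.
#' @param tick_s Time resolution, s.
#' @param window_s Spectral window, s.
#' @param baseline Trial-relative window (s) of analysis windows lying fully
#'   inside the rest period.
#' @param band,notch,order Filter settings (see [buffer_filter()]).
#' @return List of class `ersp_map`: `ersp` (freq x time matrix, percent),
#'   `freq` (Hz), `time` (trial-relative s of window end), `n_trials`.
#' @export
ersp_timefreq_map <- function(recording, events = NULL, sampling_rate = NULL,
                              center = "C3",
                              neighbors = c("F3", "P3", "T7", "Cz"),
                              freq_range = c(1, 40), tick_s = 0.1,
                              window_s = 1, baseline = NULL,
                              band = c(3, 70), notch = 50, order = 3) {
  if (inherits(recording, "eeg_recording")) {
    x <- large_laplacian(recording, center, neighbors)
    events <- recording$events
    fs <- recording$sampling_rate
  } else {
    x <- as.numeric(recording)
    if (is.null(events) || is.null(sampling_rate)) {
      stop("plain-vector input needs events and sampling_rate", call. = FALSE)
    }
    fs <- sampling_rate
  }
  xf <- buffer_filter(x, fs, band = band, notch = notch, order = order)

  rest_on <- events$onset_sample[events$label == "rest"]
  if (length(rest_on) == 0) stop("no rest events: cannot baseline", call. = FALSE)
  trial_n <- if (length(rest_on) > 1) rest_on[2] - rest_on[1] else length(x) - rest_on[1] + 1L
  trial_s <- trial_n / fs
  ready_on <- events$onset_sample[events$label == "ready"]
  rest_s <- if (length(ready_on)) (ready_on[1] - rest_on[1]) / fs else trial_s
  if (is.null(baseline)) baseline <- c(window_s, rest_s)

  rel_t <- seq(window_s, trial_s, by = tick_s)        # window end times
  win_n <- round(window_s * fs)
  keep_trials <- rest_on[rest_on + trial_n - 1L <= length(x)]
  if (length(keep_trials) == 0) stop("no complete trial in recording", call. = FALSE)

  k_sel <- NULL; acc <- NULL; n_used <- 0L
  for (t0 in keep_trials) {
    ends <- t0 - 1L + round(rel_t * fs)
    pw <- stft_power_matrix(xf, fs, ends, window_s)
    if (is.null(k_sel)) k_sel <- pw$freq >= freq_range[1] & pw$freq <= freq_range[2]
    P <- pw$power[k_sel, , drop = FALSE]
    base <- rel_t >= baseline[1] & rel_t <= baseline[2]
    ref <- rowMeans(P[, base, drop = FALSE])
    if (any(ref <= 0)) { message("trial skipped: degenerate rest reference"); next }
    e <- 100 * (P - ref) / ref
    acc <- if (is.null(acc)) e else acc + e
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable trials", call. = FALSE)
  structure(list(ersp = acc / n_used,
                 freq = (seq_len(floor(win_n / 2)) / window_s)[k_sel],
                 time = rel_t, n_trials = n_used,
                 baseline = baseline),
            class = "ersp_map")
}

#' Task-window mean ERSP at the frequency of interest
#'
#' The block-level endpoint: mean ERSP at the FOI over the task window.
#'
#' @param map An `ersp_map`.
#' @param window Trial-relative time window, s.
#' @param foi Frequency of interest, Hz.
#' @return Scalar mean ERSP (percent).
#' @export
block_average_ersp <- function(map, window = c(7, 12), foi) {
  i <- which(map$freq == foi)
  if (length(i) != 1) stop("foi is not a frequency bin of the map", call. = FALSE)
  sel <- map$time >= window[1] & map$time <= window[2]
  if (!any(sel)) stop("window outside the trial", call. = FALSE)
  mean(map$ersp[i, sel])
}
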
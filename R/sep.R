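# Somatosensory evoked potential processing: 3-500 Hz zero-phase band
# limiting, 600-ms stimulus-centered epoching, z-scoring of the epoch
# average by its pre-stimulus statistics, and extrema search within +/-3 ms
# of the nominal component latencies (N9, N13, N20).

# Nominal component definitions: montage and search-center latency.
sep_component_table <- function() {
  data.frame(name = c("N9", "N13", "N20"),
             montage = c("EPi-EPc", "C2S-Fz", "CPc-Fz"),
             latency_ms = c(9, 13, 20))
}

#' Band-limit SEP traces (3-500 Hz, zero phase)
#'
#' Fourth-order Butterworth high-pass at 3 Hz and low-pass at 500 Hz, each
#' applied forward and backward.
#'
#' @param recording A `sep_recording`.
#' @param highpass,lowpass Cutoffs in Hz.
#' @param order Butterworth order per filter.
#' @return The recording with filtered `traces`.
#' @export
filter_sep <- function(recording, highpass = 3, lowpass = 500, order = 4) {
  fs <- recording$sampling_rate
  if (fs <= 1000) stop("SEP filtering expects sampling_rate > 1000 Hz", call. = FALSE)
  hp <- signal::butter(order, highpass / (fs / 2), type = "high")
  lp <- signal::butter(order, lowpass / (fs / 2), type = "low")
  for (i in seq_len(nrow(recording$traces))) {
    y <- recording$traces[i, ] - mean(recording$traces[i, ])  # DC first
    y <- signal::filtfilt(hp, y)
    recording$traces[i, ] <- signal::filtfilt(lp, y)
  }
  recording
}

#' Epoch SEP traces around stimulus onsets
#'
#' Cuts 600-ms epochs with each stimulus onset at the center (-300 to
#' +300 ms). Onsets with insufficient data on either side are dropped with
#' a message.
#'
#' @param recording A `sep_recording` (filtered or raw).
#' @param epoch_ms Total epoch length, ms.
#' @return List of class `sep_epochs`: `epochs` (list per montage of
#'   n_epochs x n_samples matrices), `sampling_rate`, `time_ms`
#'   (epoch-relative, 0 = stimulus onset), `n_epochs`.
#' @export
epoch_sep <- function(recording, epoch_ms = 600) {
  fs <- recording$sampling_rate
  half <- round(epoch_ms / 2000 * fs)
  n <- ncol(recording$traces)
  ok <- recording$stim_onsets - half >= 1 & recording$stim_onsets + half - 1 <= n
  if (!all(ok)) {
    message(sum(!ok), " stimulus onset(s) dropped: epoch exceeds the recording")
  }
  onsets <- recording$stim_onsets[ok]
  if (length(onsets) == 0) stop("no usable epochs", call. = FALSE)
  idx <- outer(seq(-half, half - 1L), onsets, "+")
  epochs <- lapply(seq_len(nrow(recording$traces)), function(i) {
    matrix(recording$traces[i, idx], ncol = 2L * half, byrow = TRUE)
  })
  names(epochs) <- rownames(recording$traces)
  structure(list(epochs = epochs, sampling_rate = fs,
                 time_ms = seq(-half, half - 1L) / fs * 1000,
                 n_epochs = length(onsets)),
            class = "sep_epochs")
}

#' Average epochs and z-score by pre-stimulus statistics
#'
#' Epochs are averaged, then the average is z-scored using the mean and SD
#' of its own pre-stimulus (-300 to 0 ms) segment. An alternative order
#' (z-score each epoch, then average) is available.
#'
#' @param epochs A `sep_epochs` object.
#' @param montage Montage name to process.
#' @param order `"average-first"` (default, the literal processing order) or
#'   `"zscore-first"`.
#' @return List of class `sep_waveform`: `z` (z-scored averaged waveform),
#'   `time_ms`, `n_epochs`, `montage`.
#' @export
zscore_average <- function(epochs, montage,
                           order = c("average-first", "zscore-first")) {
  order <- match.arg(order)
  if (!montage %in% names(epochs$epochs)) {
    stop("montage not present: ", montage, call. = FALSE)
  }
  E <- epochs$epochs[[montage]]
  pre <- epochs$time_ms < 0
  if (sum(pre) < 2) stop("need >= 2 pre-stimulus samples", call. = FALSE)
  zs <- function(x) {
    s <- stats::sd(x[pre])
    if (s == 0) stop("zero pre-stimulus SD: degenerate input", call. = FALSE)
    (x - mean(x[pre])) / s
  }
  z <- if (order == "average-first") {
    zs(colMeans(E))
  } else {
    colMeans(t(apply(E, 1, zs)))
  }
  structure(list(z = z, time_ms = epochs$time_ms,
                 n_epochs = epochs$n_epochs, montage = montage),
            class = "sep_waveform")
}

#' Locate a SEP component by extrema search around its nominal latency
#'
#' Finds the most extreme value of the stated polarity within +/-`tol_ms` of
#' the nominal latency. Ties break to the earlier latency.
#'
#' @param waveform A `sep_waveform`.
#' @param nominal_latency_ms Nominal component latency, ms post-stimulus.
#' @param polarity `"negative"` (N components) or `"positive"`.
#' @param tol_ms Search half-width, ms.
#' @return List: `latency_ms`, `amplitude_z`.
#' @export
find_component <- function(waveform, nominal_latency_ms,
                           polarity = c("negative", "positive"), tol_ms = 3) {
  polarity <- match.arg(polarity)
  sel <- which(waveform$time_ms >= nominal_latency_ms - tol_ms &
               waveform$time_ms <= nominal_latency_ms + tol_ms)
  if (length(sel) == 0) stop("search window outside the epoch", call. = FALSE)
  v <- waveform$z[sel]
  i <- if (polarity == "negative") which.min(v) else which.max(v)
  list(latency_ms = waveform$time_ms[sel[i]], amplitude_z = v[i])
}

#' Extract all SEP components from a recording
#'
#' Full chain: band limiting, epoching, averaged-then-z-scored waveforms per
#' montage, extrema search at the nominal latencies (N9 at 9 ms on EPi-EPc,
#' N13 at 13 ms on C2S-Fz, N20 at 20 ms on CPc-Fz). Missing montages yield a
#' partial result with a warning.
#'
#' @param recording A `sep_recording`.
#' @param components Data frame of component definitions (`name`, `montage`,
#'   `latency_ms`); defaults to the N9/N13/N20 table.
#' @param filter Apply [filter_sep()] first.
#' @param tol_ms Extrema search half-width, ms.
#' @return Data frame: `component`, `montage`, `latency_ms`, `amplitude_z`,
#'   `n_epochs`.
#' @export
extract_all <- function(recording, components = sep_component_table(),
                        filter = TRUE, tol_ms = 3) {
  if (filter) recording <- filter_sep(recording)
  ep <- epoch_sep(recording)
  have <- components$montage %in% names(ep$epochs)
  if (!all(have)) {
    warning("missing montage(s): ",
            paste(components$montage[!have], collapse = ", "),
            "; returning partial component set")
  }
  comp <- components[have, , drop = FALSE]
  out <- lapply(seq_len(nrow(comp)), function(i) {
    wf <- zscore_average(ep, comp$montage[i])
    fc <- find_component(wf, comp$latency_ms[i], "negative", tol_ms)
    data.frame(component = comp$name[i], montage = comp$montage[i],
               latency_ms = fc$latency_ms, amplitude_z = fc$amplitude_z,
               n_epochs = ep$n_epochs)
  })
  do.call(rbind, out)
}
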
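# Minimal European Data Format (EDF) writer/reader for continuous
# recordings (16-bit samples, per-channel physical scaling, 1-s data
# records), plus delimiter-separated sidecar event tables. Signals whose
# length is not a whole number of records are zero-padded on write.

edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

edf_num <- function(x, width = 8) {
  for (d in c(7, 4, 2)) {
    s <- formatC(x, format = "g", digits = d, width = 1)
    if (nchar(s) <= width) break
  }
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' @param recording An `eeg_recording` or `sep_recording` (any list with a
#'   channels x samples `signal` or `traces` matrix, `sampling_rate` and
#'   channel names).
#' @param path Output file path.
#' @param physical_dim Physical dimension label (default uV).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_dim = "uV") {
  sig <- if (!is.null(recording$signal)) recording$signal else recording$traces
  labels <- rownames(sig)
  if (is.null(labels)) labels <- recording$channel_labels
  fs <- recording$sampling_rate
  ns <- nrow(sig)
  n_rec <- ceiling(ncol(sig) / fs)
  if (ncol(sig) < n_rec * fs) {
    sig <- cbind(sig, matrix(0, ns, n_rec * fs - ncol(sig)))
  }

  pmin_ <- apply(sig, 1, min); pmax_ <- apply(sig, 1, max)
  flat <- pmax_ - pmin_ == 0
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  # the header stores limited-precision ASCII; widen the physical range by
  # 0.5% per side before rounding and scale with the stored (parsed-back)
  # values, so reading back is exact to about one digital step
  margin <- 0.005 * (pmax_ - pmin_)
  pmin_str <- vapply(pmin_ - margin, edf_num, "")
  pmax_str <- vapply(pmax_ + margin, edf_num, "")
  pmin_ <- as.numeric(trimws(pmin_str))
  pmax_ <- as.numeric(trimws(pmax_str))
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_pad("0", 8))                          # version
  wr(edf_pad("synthetic", 80))                 # patient id
  wr(edf_pad("smrpipe", 80))                   # recording id
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(as.character(256 * (1 + ns)), 8)) # header bytes
  wr(edf_pad("", 44))
  wr(edf_pad(as.character(n_rec), 8))
  wr(edf_pad("1", 8))                          # record duration, s
  wr(edf_pad(as.character(ns), 4))
  wr(paste0(vapply(labels, edf_pad, "", width = 16), collapse = ""))
  wr(strrep(" ", 80 * ns))                     # transducer
  wr(paste0(rep(edf_pad(physical_dim, 8), ns), collapse = ""))
  wr(paste0(pmin_str, collapse = ""))
  wr(paste0(pmax_str, collapse = ""))
  wr(paste0(rep(edf_pad(as.character(dmin), 8), ns), collapse = ""))
  wr(paste0(rep(edf_pad(as.character(dmax), 8), ns), collapse = ""))
  wr(strrep(" ", 80 * ns))                     # prefiltering
  wr(paste0(rep(edf_pad(as.character(fs), 8), ns), collapse = ""))
  wr(strrep(" ", 32 * ns))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1) * fs + seq_len(fs)
    for (ch in seq_len(ns)) {
      dig <- round((sig[ch, cols] - pmin_[ch]) * scale[ch] + dmin)
      writeBin(as.integer(clamp(dig, dmin, dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the fixed-layout EDF header and 16-bit data records, restoring
#' physical units from the per-channel scaling.
#'
#' @param path EDF file path.
#' @param events Optional event table (see [read_events()]) to attach.
#' @return List of class `eeg_recording`: `signal` (channels x samples),
#'   `sampling_rate`, `channel_labels`, `events`.
#' @export
read_edf <- function(path, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (nchar(s, type = "bytes") < n) {
      stop("truncated EDF header at byte ", seek(con), call. = FALSE)
    }
    trimws(s)
  }
  rd(8)                                        # version
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: signal count", call. = FALSE)
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16)
  fields(80)
  fields(8)                                    # physical dimension
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))                 # samples per record
  fields(32)
  if (length(unique(spr / rec_dur)) != 1) {
    stop("channels disagree on sampling rate", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  expected <- as.integer(seek(con))
  if (!is.na(header_bytes) && header_bytes != expected) {
    stop("malformed EDF header: stated size ", header_bytes,
         " != parsed size ", expected, call. = FALSE)
  }

  sig <- matrix(0, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[ch]) {
        stop("truncated EDF data at byte ", seek(con), call. = FALSE)
      }
      sig[ch, (r - 1) * spr[ch] + seq_len(spr[ch])] <-
        (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  if (is.null(events)) {
    warning("no event table attached; recording has an empty event list")
    events <- data.frame(onset_sample = integer(0), label = character(0))
  }
  structure(list(signal = sig, sampling_rate = fs, channel_labels = labels,
                 events = events),
            class = "eeg_recording")
}

#' Write / read a sidecar event table
#'
#' Tab-separated table with columns `onset_sample` (1-based) and `label`
#' (plus any extra columns such as `trial`).
#'
#' @param events Event data frame.
#' @param path File path.
#' @return The path (write) or the event data frame (read).
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
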
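# Online feedback chain: spatial filter, temporal filters, short-time
# spectra, ERSP arithmetic, FOI calibration, smoothing, frame mapping and
# the causal closed-loop replay.

fake_rec <- function(mat, labels, fs = 1000) {
  structure(list(signal = mat, sampling_rate = fs, channel_labels = labels,
                 events = data.frame(onset_sample = 1L, label = "rest")),
            class = "eeg_recording")
}

test_that("large Laplacian is center minus neighbor mean", {
  labels <- c("C3", "F3", "P3", "T7", "Cz")
  m <- matrix(rep(c(4, 1, 2, 3, 6), 10), nrow = 5)
  rownames(m) <- labels
  rec <- fake_rec(m, labels)
  expect_equal(large_laplacian(rec), rep(1, 10))          # 4 - mean(1,2,3,6)
  same <- fake_rec(matrix(5, 5, 10, dimnames = list(labels, NULL)), labels)
  expect_equal(large_laplacian(same), rep(0, 10))         # common-mode rejection
  m2 <- m; m2[2:5, ] <- 0; rec2 <- fake_rec(m2, labels)
  expect_equal(large_laplacian(rec2), m2["C3", ])         # identity
  expect_error(large_laplacian(rec, neighbors = c("F3", "F4")), "F4")
})

test_that("buffer filter is zero-phase, notches 50 Hz and rejects DC", {
  fs <- 1000
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  y10 <- buffer_filter(x10, fs)
  cc <- stats::ccf(y10[1000:4000], x10[1000:4000], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)              # peak at lag 0
  x50 <- sin(2 * pi * 50 * t)
  y50 <- buffer_filter(x50, fs)
  mid <- 1000:4000
  expect_lt(sqrt(mean(y50[mid]^2)) / sqrt(mean(x50[mid]^2)), 0.01)
  ydc <- buffer_filter(rep(2, 5 * fs), fs)
  expect_lt(max(abs(ydc[mid])), 1e-3)             # 3 Hz high-pass edge
  expect_error(buffer_filter(rep(0, 10), fs), "short")
})

test_that("short-time power concentrates at the tone frequency and scales", {
  fs <- 1000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  pw <- stft_power(sin(2 * pi * 10 * t), fs)
  expect_equal(pw$freq[which.max(pw$power)], 10)
  expect_gt(pw$power[10] / pw$power[20], 100)
  expect_equal(stft_power(numeric(fs), fs)$power, rep(0, 500))
  pw2 <- stft_power(2 * sin(2 * pi * 10 * t), fs)
  expect_equal(pw2$power, 4 * pw$power)
  expect_error(stft_power(numeric(100), fs), "window")
})

test_that("reference is the per-bin mean over rest samples", {
  p1 <- structure(list(freq = 1:3, power = c(2, 2, 2)), class = "power_sample")
  p2 <- structure(list(freq = 1:3, power = c(4, 2, 0)), class = "power_sample")
  expect_equal(compute_reference(list(p1, p2)), c(3, 2, 1))
  expect_equal(compute_reference(list(p1)), c(2, 2, 2))
  expect_error(compute_reference(list()), "empty")
})

test_that("ERSP arithmetic and degenerate reference handling", {
  ref <- c(10, 10, 10)
  expect_equal(ersp(ref, ref), c(0, 0, 0))
  expect_equal(ersp(0.7 * ref, ref), rep(-30, 3))
  expect_equal(ersp(2 * ref, ref), rep(100, 3))
  expect_equal(ersp(c(0, 0, 0), ref), rep(-100, 3))
  expect_error(ersp(ref, c(10, 0, 10)), "positive")
  expect_error(ersp(1:2, 1:3), "bins")
})

test_that("scalar SMR: alpha-band mean and FOI-bin modes", {
  freq <- 1:20
  e <- rep(0, 20); e[8:13] <- c(-10, -20, -30, -40, -50, -60)
  expect_equal(smr_alpha(e, freq), -35)
  expect_equal(smr_alpha(rep(-20, 20), freq), -20)
  expect_equal(smr_alpha(e, freq, mode = "foi", foi = 11), -40)
  expect_error(smr_alpha(e, freq, mode = "foi"), "foi")
})

test_that("FOI calibration finds the injected bin, breaks ties low, warns flat", {
  # bin-resolved injection: pure tone exactly on the 10 Hz bin
  rec <- small_eeg(erd_depth = 0.5, n_trials = 4, iaf_true = 10,
                   alpha_linewidth = 0)
  map <- ersp_timefreq_map(rec)
  expect_equal(calibrate_foi(map), 10)
  flat <- list(ersp = matrix(1, 6, 5), freq = 8:13, time = seq(7, 12, length.out = 5))
  expect_warning(foi <- calibrate_foi(flat), "negative")
  expect_equal(foi, 8)                                    # deterministic tie-break
  tie <- list(ersp = matrix(c(-5, 0, 0, 0, -5, 0), 6, 5), freq = 8:13,
              time = seq(7, 12, length.out = 5))
  expect_equal(calibrate_foi(tie), 8)                     # 8 and 12 tie -> lowest
})

test_that("smoothing averages the latest at most 10 samples", {
  expect_equal(smooth_smr(rep(3, 25)), 3)
  expect_equal(smooth_smr(1:10), 5.5)
  expect_equal(smooth_smr(1:11), 6.5)                     # window slides
  expect_equal(smooth_smr(c(0, -30, -60)), -30)
  expect_error(smooth_smr(numeric(0)), "empty")
})

test_that("frame mapping anchors, midpoint rounding and clipping", {
  cal <- feedback_calibration(foi = 10, p25 = -40, p75 = 5)
  expect_equal(map_to_frame(-40, cal), 20L)               # p25 -> abducted
  expect_equal(map_to_frame(5, cal), 1L)                  # p75 -> frame 1
  expect_equal(map_to_frame(-17.5, cal), 11L)             # midpoint, half-up
  expect_equal(map_to_frame(-100, cal), 20L)              # clipped
  expect_equal(map_to_frame(50, cal), 1L)
  expect_error(map_to_frame(0, feedback_calibration(10, 1, 1)), "degenerate")
  expect_error(feedback_calibration(10, 5, -5), "p25")
})

test_that("closed-loop replay is deterministic and tracks simulated ERD", {
  rec <- small_eeg(erd_depth = 0.5, n_trials = 3, seed = 55)
  cal <- feedback_calibration(foi = 10, p25 = -40, p75 = 5)
  tr <- run_closed_loop_replay(rec, cal)
  expect_identical(tr, run_closed_loop_replay(rec, cal))
  rel <- tr$tick_s %% 17
  task <- rel > 7 & rel <= 12
  rest <- rel > 1.5 & rel <= 5
  expect_lt(mean(tr$smoothed_smr[task], na.rm = TRUE),
            mean(tr$smoothed_smr[rest], na.rm = TRUE))
  expect_true(all(tr$frame >= 1 & tr$frame <= 20, na.rm = TRUE))
  expect_true(all(tr$raw_smr >= -100, na.rm = TRUE))
})

test_that("replay is causal: truncation leaves earlier ticks unchanged", {
  rec <- small_eeg(erd_depth = 0.5, n_trials = 2, seed = 56)
  cal <- feedback_calibration(foi = 10, p25 = -40, p75 = 5)
  full <- run_closed_loop_replay(rec, cal)
  cut_n <- 20 * 1000
  rec2 <- rec
  rec2$signal <- rec$signal[, 1:cut_n]
  rec2$events <- rec$events[rec$events$onset_sample <= cut_n, ]
  part <- run_closed_loop_replay(rec2, cal)
  keep <- full$tick_s <= 20
  expect_equal(part, full[keep, ], ignore_attr = TRUE)
})

test_that("sham replay frames do not follow the displayed subject's ERD", {
  # feedback computed from an independent flat recording: correlation of the
  # trace with the subject's own task structure is nil by construction
  own <- small_eeg(erd_depth = 0.6, n_trials = 2, seed = 57)
  other <- small_eeg(erd_depth = 0, n_trials = 2, seed = 58)
  cal <- feedback_calibration(foi = 10, p25 = -40, p75 = 5)
  sham_tr <- run_closed_loop_replay(other, cal)
  rel <- sham_tr$tick_s %% 17
  task <- rel > 7 & rel <= 12
  rest <- rel > 1.5 & rel <= 5
  gap <- mean(sham_tr$smoothed_smr[task], na.rm = TRUE) -
    mean(sham_tr$smoothed_smr[rest], na.rm = TRUE)
  own_tr <- run_closed_loop_replay(own, cal)
  own_gap <- mean(own_tr$smoothed_smr[task], na.rm = TRUE) -
    mean(own_tr$smoothed_smr[rest], na.rm = TRUE)
  expect_lt(own_gap, -20)
  expect_gt(gap, own_gap / 4)                             # no comparable ERD
})
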
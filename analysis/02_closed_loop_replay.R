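#!/usr/bin/env Rscript
# Stage 2: replay the online feedback computation on the simulated
# open-loop block. The FOI is calibrated from the open-loop time-frequency
# map (most negative task-period alpha bin), the 25th/75th SMR percentiles
# anchor the frame mapping, and the causal per-tick chain produces the
# feedback trace (raw SMR, 10-sample smoothed SMR, frame 1-20).

library(smrpipe)

dat <- file.path("results", "data")
eeg <- read_edf(file.path(dat, "eeg_openloop.edf"),
                events = read_events(file.path(dat, "eeg_openloop_events.tsv")))

map <- ersp_timefreq_map(eeg)
foi <- calibrate_foi(map)
message("calibrated FOI: ", foi, " Hz")

open_trace <- run_closed_loop_replay(eeg, calibration = NULL, mode = "band")
cal <- calibrate_percentiles(stats::na.omit(open_trace$smoothed_smr), foi)
message(sprintf("SMR percentiles: p25 = %.1f%%, p75 = %.1f%%", cal$p25, cal$p75))

trace <- run_closed_loop_replay(eeg, cal)
utils::write.table(trace, file.path("results", "feedback_trace.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)

rel <- trace$tick_s %% 17
task <- rel > 7 & rel <= 12
rest <- rel > 1.5 & rel <= 5
message(sprintf("mean smoothed SMR: rest %.1f%%, task %.1f%% (ERD induces the gap)",
                mean(trace$smoothed_smr[rest], na.rm = TRUE),
                mean(trace$smoothed_smr[task], na.rm = TRUE)))
message(sprintf("frame usage: median rest %d, median task %d (20 = fully abducted)",
                stats::median(trace$frame[rest], na.rm = TRUE),
                stats::median(trace$frame[task], na.rm = TRUE)))
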
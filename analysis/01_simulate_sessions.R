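#!/usr/bin/env Rscript
# Stage 1: simulate one participant's study data with known ground truth --
# a 20-trial motor-imagery EEG block (IAF 10 Hz, 40% task ERD), a
# 1000-stimulus median-nerve SEP session and a 5-block typing session --
# and persist everything as EDF + sidecar tables for the later stages.

library(smrpipe)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

eeg_cfg <- eeg_sim_config(erd_depth = 0.4, iaf_true = 10, seed = 101L)
eeg <- generate_eeg_session(eeg_cfg)
write_edf(eeg, file.path(out, "eeg_openloop.edf"))
write_events(eeg$events, file.path(out, "eeg_openloop_events.tsv"))
message(sprintf("EEG: %d channels x %d s at %g Hz, %d trials, true ERD %.0f%% at %g Hz",
                nrow(eeg$signal), ncol(eeg$signal) / eeg$sampling_rate,
                eeg$sampling_rate, eeg_cfg$n_trials,
                100 * eeg_cfg$erd_depth, eeg_cfg$iaf_true))

sep_cfg <- sep_sim_config(seed = 102L)
sep <- generate_sep_session(sep_cfg)
write_edf(sep, file.path(out, "sep_eval1.edf"))
write_events(data.frame(onset_sample = sep$stim_onsets, label = "stim"),
             file.path(out, "sep_eval1_events.tsv"))
message(sprintf("SEP: %d stimuli at %g Hz on %d montages (%.0f s at %g Hz)",
                sep_cfg$n_stimuli, sep_cfg$stim_rate, nrow(sep$traces),
                ncol(sep$traces) / sep$sampling_rate, sep$sampling_rate))

beh_cfg <- behavior_sim_config(seed = 103L)
beh <- generate_behavior(beh_cfg)
utils::write.table(beh, file.path(out, "behavior_eval1.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
message(sprintf("Behavior: %d word trials, true curve a=%.2f b=%.2f c=%.2f",
                nrow(beh), beh_cfg$a_true, beh_cfg$b_true, beh_cfg$c_true))
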
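#!/usr/bin/env Rscript
# Stage 4: SEP component quantification. Band limiting (3-500 Hz, zero
# phase), 600-ms stimulus-centered epochs, z-scoring of the epoch average
# by its pre-stimulus statistics, and extrema search within +/-3 ms of the
# nominal N9 / N13 / N20 latencies on their montages.

library(smrpipe)

dat <- file.path("results", "data")
ev <- read_events(file.path(dat, "sep_eval1_events.tsv"))
rec <- read_edf(file.path(dat, "sep_eval1.edf"), events = ev)
rec$traces <- rec$signal
rec$montages <- rec$channel_labels
rec$stim_onsets <- ev$onset_sample
class(rec) <- "sep_recording"

comp <- extract_all(rec)
utils::write.table(comp, file.path("results", "sep_components.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
print(comp, row.names = FALSE)
message("negative z amplitudes are the component deflections; ",
        "latencies should sit at the configured 9 / 13 / 20 ms")
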
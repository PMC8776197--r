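#!/usr/bin/env Rscript
# Simulate the stimulus-locked EEG study: 32-channel recordings with the
# 7-landscape x 2-repeat block design, written as EDF + events TSV.
# A 5-subject study keeps the demonstration tractable; raise N_SUBJECTS to
# 20 for the full design.

library(eegscape)

N_SUBJECTS <- 5
OUT <- "results/raw"

cfg <- load_config()
cfg$synthetic$n_subjects <- N_SUBJECTS

files <- run_simulation(cfg, OUT)
cat(sprintf("wrote %d recordings to %s\n", nrow(files), OUT))
cat(sprintf("session length: %.0f s each; sampling rate %g Hz\n",
            recording_duration(read_edf(files$edf[1])),
            cfg$synthetic$rate_hz))
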
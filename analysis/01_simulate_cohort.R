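#!/usr/bin/env Rscript
# Simulate the study cohort: 13 weakly-coupled ("patient-like") vs 14
# strongly-coupled ("control-like") subjects of epoched 16-channel EEG,
# written in the delimited + JSON-sidecar container the pipeline reads.
# Epochs are kept short (110 samples, 16 pre-stimulus) so the full pairwise
# coupling analysis downstream runs in seconds per subject.

library(jdnet)

spec <- cohort_spec(channels = 16L, epoch_len = 110L, prestim = 16L,
                    between_a = 0.0, between_b = 0.6,
                    model = source_model(16L, 8L, noise_sd = 0.5),
                    seed = 20240L)
cohort <- generate_cohort(spec)
write_cohort(cohort, "scratch/cohort")

neps <- vapply(cohort, `[[`, 0L, "n_epochs")
cat(sprintf("wrote %d subjects to scratch/cohort (%d group A, %d group B)\n",
            length(cohort), spec$n_a, spec$n_b))
cat(sprintf("epochs per subject: %d-%d (median %d)\n",
            min(neps), max(neps), as.integer(median(neps))))
cat("group A mixes no between-module source variance; group B mixes 0.6\n")
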
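#!/usr/bin/env Rscript
# Generate the synthetic exercise-trial cohort: 36 data streams (18
# experiments x 2 CGM sensors, 6 patients), of which 9 carry faulty blocks,
# mirroring the clinic's yield. One CSV per stream.

library(ecgm)

SEED <- 20190831
out <- "results/analysis/streams"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config(n_streams = 36, n_faulty_streams = 9,
                    seed = derive_seed(SEED, "simulate"))
streams <- generate_cohort(cfg)
for (s in streams) write_trial(s, file.path(out, paste0(s$stream_id, ".csv")))

n_ref <- sum(!is.na(streams[[1]]$data$pg_mgdl))
cat(sprintf("wrote %d trial streams to %s\n", length(streams), out))
cat(sprintf("each stream: %d minutes, %d reference samples, %d exercise minutes\n",
            nrow(streams[[1]]$data), n_ref, sum(streams[[1]]$data$exercise)))
cat(sprintf("generative error model: E = %.2f * dFME %+.3f * dMTM (mg/dL)\n",
            cfg$true_coefficients[["FME"]], cfg$true_coefficients[["MTM"]]))
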
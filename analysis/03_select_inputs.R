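#!/usr/bin/env Rscript
# Four-criterion backwards elimination of the eleven wearable inputs:
# availability, redundancy (|r| >= 0.85), exercise relevance, and the
# cross-validated MARD loop.

library(ecgm)

SEED <- 20190831
out <- "results/analysis"
files <- sort(list.files(file.path(out, "streams"), pattern = "\\.csv$",
                         full.names = TRUE))
streams <- lapply(files, read_trial)
prepped <- lapply(qc_filter(streams)$retained, remove_baseline)

pairs <- do.call(rbind, lapply(prepped, pair_with_reference))
r <- correlation_matrix(pairs, intersect(SIGNAL_CODES, names(pairs)))
utils::write.csv(round(r, 3), file.path(out, "signal_correlations.csv"))

trace <- select_inputs(prepped, seed = derive_seed(SEED, "select"))
write_trace(trace, file.path(out, "elimination_trace.json"))

cat("elimination sequence:\n")
print(trace)
cat(sprintf("\nfinal model inputs: %s (order %d)\n",
            paste(trace$surviving, collapse = ", "), length(trace$surviving)))
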
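#!/usr/bin/env Rscript
# Ingest the trial CSVs, discard streams with excessive faulty data, compute
# per-trial rest-period baselines and pooled signal availability.

library(ecgm)

out <- "results/analysis"
files <- sort(list.files(file.path(out, "streams"), pattern = "\\.csv$",
                         full.names = TRUE))
stopifnot(length(files) > 0)
streams <- lapply(files, read_trial)

qc <- qc_filter(streams)
utils::write.csv(qc$log, file.path(out, "qc_log.csv"), row.names = FALSE)
cat(sprintf("QC: retained %d of %d streams (%s)\n", length(qc$retained),
            length(streams),
            paste(sprintf("%s: %s", qc$log$stream_id, qc$log$reason)[1:3],
                  collapse = "; ")))

bt <- baseline_table(qc$retained)
utils::write.csv(bt, file.path(out, "baselines.csv"), row.names = FALSE)

prepped <- lapply(qc$retained, remove_baseline, baselines = bt)
av <- pooled_availability(prepped)
utils::write.csv(data.frame(signal = names(av), availability_pct = round(av, 1)),
                 file.path(out, "availability.csv"), row.names = FALSE)
cat("pooled signal availability (%):\n")
print(round(av, 1))
cat(sprintf("paired CGM-reference samples: %d\n",
            nrow(do.call(rbind, lapply(prepped, pair_with_reference)))))
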
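#!/usr/bin/env Rscript
# Clinical-accuracy grading of the corrected CGM: Clarke error grid, Parkes
# (type-1 consensus) error grid, and the ISO 15197:2013 acceptance region,
# by period and source, on the pooled cross-validation pairs.

library(ecgm)

out <- "results/analysis"
vp <- utils::read.csv(file.path(out, "validation_pairs.csv"))
vp$in_exercise <- as.logical(vp$in_exercise)

for (method in c("clarke", "parkes", "iso")) {
  z <- zone_summary(vp, method)
  utils::write.csv(z, file.path(out, paste0("ega_", method, ".csv")),
                   row.names = FALSE)
}

pick <- function(method, period, source, zone) {
  z <- utils::read.csv(file.path(out, paste0("ega_", method, ".csv")))
  z$pct[z$period == period & z$source == source & z$zone == zone]
}
cat("zone A / ISO-OK allocation, exercise period (CGM -> eCGM):\n")
cat(sprintf("  Clarke A: %.1f%% -> %.1f%%\n",
            pick("clarke", "exercise", "cgm", "A"),
            pick("clarke", "exercise", "ecgm", "A")))
cat(sprintf("  Parkes A: %.1f%% -> %.1f%%\n",
            pick("parkes", "exercise", "cgm", "A"),
            pick("parkes", "exercise", "ecgm", "A")))
cat(sprintf("  ISO OK:   %.1f%% -> %.1f%%\n",
            pick("iso", "exercise", "cgm", "OK"),
            pick("iso", "exercise", "ecgm", "OK")))
cat(sprintf("  ISO OK total: %.1f%% -> %.1f%%\n",
            pick("iso", "total", "cgm", "OK"),
            pick("iso", "total", "ecgm", "OK")))
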
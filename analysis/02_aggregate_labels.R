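#!/usr/bin/env Rscript
# Aggregate projection volumes into per-pair connectivity values
# (median over a target's voxels per experiment, max across experiments)
# and label every ordered pair. Writes results/<study>/pairs.csv and the
# four-table SQLite store.

source(file.path("analysis", "00_config.R"))

for (name in c("binary", "multiclass")) {
  cfg <- get(paste0(name, "_config"))
  pairs <- run_stage("label", cfg)
  sizes <- table(pairs$label, useNA = "ifany")
  message(sprintf("%s study: class sizes %s", name,
                  paste(names(sizes), sizes, sep = "=", collapse = " ")))
}
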
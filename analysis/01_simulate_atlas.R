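#!/usr/bin/env Rscript
# Simulate the two synthetic atlases and write them to disk in the same
# formats an ingested atlas would use: per-gene raw float32 expression
# volumes, NRRD projection volumes, annotation CSVs and the structure-graph
# JSON. Downstream stages read only these files.

source(file.path("analysis", "00_config.R"))

for (cfg in list(binary = binary_config, multiclass = multiclass_config)) {
  run_stage("generate", cfg)
}

# quick look at the planted signal of the binary atlas
atlas <- generate_atlas(binary_config$synth)
conn <- atlas$truth$pair_connectivity
off <- !is.na(conn)
message(sprintf(
  "binary atlas: %d ordered pairs, %.0f%% unconnected, nonzero connectivity spanning [%.3g, %.3g]",
  sum(off), 100 * mean(conn[off] == 0),
  min(conn[off][conn[off] > 0]), max(conn[off])))
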
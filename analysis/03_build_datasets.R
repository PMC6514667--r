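#!/usr/bin/env Rscript
# Build the normalized Source-Target vector datasets: M voxels per region
# per labeled pair, concatenated expression profiles (source half first),
# per-class caps, stratified 72/8/20 split, min-max scaling fitted on the
# training partition. Writes results/<study>/dataset/{train,validation,test}.csv
# plus a manifest with the scaler and seeds.

source(file.path("analysis", "00_config.R"))

for (name in c("binary", "multiclass")) {
  built <- run_stage("build", get(paste0(name, "_config")))
  message(sprintf("%s study: %d vectors of length %d", name,
                  built$log$n_vectors_after_caps,
                  ncol(built$split$train$features)))
}
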
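#!/usr/bin/env Rscript
# Train and evaluate the binary connected-vs-unconnected classifier:
# 100 epochs, batch size 32, Nadam (lr 0.002, decay 0.004). Writes the
# trained model, per-epoch history, and the evaluation report (confusion
# matrix, precision/recall/F1, ROC/AUC) under results/binary/.

source(file.path("analysis", "00_config.R"))

run_stage("train", binary_config)
report <- run_stage("evaluate", binary_config)
print(report)

roc_path <- file.path(binary_config$out_dir, "roc.csv")
write.csv(report$roc, roc_path, row.names = FALSE)
message("ROC curve written to ", roc_path)
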
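#!/usr/bin/env Rscript
# Train and evaluate the 3-class classifier (unconnected / weakly / strongly
# connected): 200 epochs, batch size 6, softmax head with categorical
# cross-entropy. Writes model, history and evaluation report under
# results/multiclass/.

source(file.path("analysis", "00_config.R"))

run_stage("train", multiclass_config)
report <- run_stage("evaluate", multiclass_config)
print(report)
message(sprintf("macro-F1: %.3f",
                mean(report$per_class$f1, na.rm = TRUE)))
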
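# Shared configuration for the analysis scripts.
#
# Two studies over synthetic atlases:
#   binary     - 8 regions, default noise; connected vs unconnected pairs
#   multiclass - 12 regions, moderate expression noise, so all three
#                connectivity strata (unconnected / weak / strong) are
#                populated well enough to learn
#
# Each study writes everything under results/<study>/.

library(voxconn)

SEED <- 1L

binary_config <- pipeline_config(
  out_dir = file.path("results", "binary"),
  synth = synthetic_config(seed = SEED),
  scheme = label_scheme("binary"),
  build = build_config(M = 10L, per_class_cap = c("0" = Inf, "1" = Inf),
                       seed = SEED),
  mlp_args = list(epochs = 100L, batch_size = 32L, seed = SEED))

multiclass_config <- pipeline_config(
  out_dir = file.path("results", "multiclass"),
  synth = synthetic_config(n_regions = 12L, noise_sd = 0.3, seed = SEED),
  scheme = label_scheme("multiclass"),
  build = build_config(M = 10L,
                       per_class_cap = c("0" = Inf, "1" = Inf, "2" = Inf),
                       seed = SEED),
  # no dropout: at ~1000 training vectors the default rates, sized for
  # datasets of tens of thousands of vectors, stall convergence
  mlp_args = list(epochs = 200L, batch_size = 6L,
                  dropout_rates = c(0, 0, 0), seed = SEED))
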
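# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default small synthetic atlas (8 regions, 50 genes, 16x12x14 grid)
small_atlas <- function() {
  cached("small_atlas", generate_atlas(synthetic_config(seed = 1L)))
}

# noiseless atlas: every stochastic term off, for exact round-trips
noiseless_atlas <- function() {
  cached("noiseless_atlas", generate_atlas(
    synthetic_config(seed = 2L, noise_sd = 0, jitter = 0,
                     proj_noise_sd = 0)))
}

# a tiny hand-checkable expression matrix: G genes x V voxels, values i + j/10
toy_expression <- function(G = 4L, V = 6L) {
  expression_matrix(outer(seq_len(G), seq_len(V) / 10, `+`),
                    gene_ids = seq_len(G))
}

# brute-force reference for the median-then-max aggregation: explicit sort
brute_force_pair_value <- function(projections, target_idx) {
  medians <- vapply(projections, function(p) {
    v <- sort(p[target_idx])
    n <- length(v)
    if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
  }, numeric(1))
  m <- medians[1]
  for (x in medians[-1]) if (x > m) m <- x
  m
}
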
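# Synthetic-atlas generator: Allen-style volumetric data with a planted,
# tunable expression<->connectivity signal, so that aggregation, labeling,
# dataset construction and classification are all testable without any
# external download.

#' Configuration for the synthetic atlas generator
#'
#' Describes a simulated brain: a coarse expression grid (200 um style), a
#' fine projection grid at exactly twice the voxel density per axis (100 um
#' style), `n_regions` axis-aligned block regions, `n_genes` expression
#' volumes and a set of tracer-injection experiments per source region.
#'
#' The planted signal works through a latent embedding per region: region
#' pairs whose embeddings are similar receive higher connectivity, and each
#' region's mean expression profile is a linear readout of its embedding, so
#' expression carries information about connectivity exactly when
#' `effect_size > 0`.
#'
#' @param n_regions number of brain regions (each gets >= 1 coarse voxel).
#' @param grid_dims_expr integer triple; coarse (expression) grid dimensions.
#' @param n_genes number of gene expression volumes `G`.
#' @param latent_dim dimension of the latent region embeddings; must not
#'   exceed `n_genes`.
#' @param effect_size strength of the expression-connectivity coupling;
#'   `0` makes expression statistically independent of connectivity.
#' @param noise_sd standard deviation of the per-voxel Gaussian expression
#'   noise (truncated at zero).
#' @param n_injections_per_source tracer injections simulated per source
#'   region.
#' @param frac_unconnected fraction of ordered region pairs whose
#'   connectivity is exactly zero.
#' @param jitter amplitude of the multiplicative experiment-level factor,
#'   drawn from `U(1 - jitter, 1]`; `0` means every experiment reports the
#'   planted value exactly, so the max-over-medians rule recovers it.
#' @param proj_noise_sd standard deviation of per-voxel projection noise
#'   (truncated at zero).
#' @param seed integer seed; the whole atlas is a deterministic function of
#'   the configuration including this seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 8L,
                             grid_dims_expr = c(16L, 12L, 14L),
                             n_genes = 50L,
                             latent_dim = 4L,
                             effect_size = 5,
                             noise_sd = 0.5,
                             n_injections_per_source = 3L,
                             frac_unconnected = 0.4,
                             jitter = 0.3,
                             proj_noise_sd = 0.005,
                             seed = 1L) {
  n_regions <- stopifnot_count(n_regions, "n_regions")
  n_genes <- stopifnot_count(n_genes, "n_genes")
  latent_dim <- stopifnot_count(latent_dim, "latent_dim")
  n_injections_per_source <- stopifnot_count(n_injections_per_source,
                                             "n_injections_per_source")
  if (length(grid_dims_expr) != 3L || any(grid_dims_expr < 1) ||
      any(grid_dims_expr != as.integer(grid_dims_expr))) {
    stop("`grid_dims_expr` must be a triple of positive integers",
         call. = FALSE)
  }
  grid_dims_expr <- as.integer(grid_dims_expr)
  if (prod(grid_dims_expr) < n_regions) {
    stop("grid too small: product(grid_dims_expr) must be >= n_regions",
         call. = FALSE)
  }
  if (latent_dim > n_genes) {
    stop("invalid configuration: `latent_dim` must not exceed `n_genes`",
         call. = FALSE)
  }
  stopifnot_scalar_number(effect_size, "effect_size", min = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(frac_unconnected, "frac_unconnected", 0, 1)
  stopifnot_scalar_number(jitter, "jitter", 0, 1)
  stopifnot_scalar_number(proj_noise_sd, "proj_noise_sd", min = 0)
  seed <- stopifnot_count(seed, "seed", min = 0L)

  structure(
    list(n_regions = n_regions,
         grid_dims_expr = grid_dims_expr,
         grid_dims_conn = 2L * grid_dims_expr,
         n_genes = n_genes,
         latent_dim = latent_dim,
         effect_size = effect_size,
         noise_sd = noise_sd,
         n_injections_per_source = n_injections_per_source,
         frac_unconnected = frac_unconnected,
         jitter = jitter,
         proj_noise_sd = proj_noise_sd,
         seed = seed),
    class = "synthetic_config")
}

# Baseline connectivity scale: a latent score of 0 maps to this value, chosen
# so that typical scores straddle the 0.006 / 0.1 labeling thresholds.
.CONN_SCALE <- 0.05
# SD of the pair-level latent noise added to effect_size * similarity.
.PAIR_NOISE_SD <- 0.3

#' Generate the ground truth of a synthetic atlas
#'
#' Draws latent region embeddings, derives each region's mean expression
#' profile as a linear readout of its embedding, and assigns every ordered
#' region pair a connectivity value through a latent score
#' `effect_size * similarity(s, t) + noise`. The `frac_unconnected` share of
#' pairs with the lowest scores is set to exactly zero; the rest map to
#' `0.05 * exp(score)`. Coupling the zero set to the same score (rather than
#' masking pairs independently at random) is what makes the planted label a
#' function of expression: with `effect_size = 0` the score is pure noise, so
#' which pairs are unconnected is independent of expression, while with a
#' large `effect_size` both the zero set and the magnitude are driven by
#' embedding similarity.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `ground_truth` with elements
#'   `region_embeddings` (n_regions x latent_dim),
#'   `region_mean_profiles` (n_regions x n_genes),
#'   `pair_connectivity` (n_regions x n_regions matrix, `NA` diagonal),
#'   and the generating `config`.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_regions
  d <- config$latent_dim
  G <- config$n_genes

  with_seed(config$seed, {
    emb <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
    loading <- matrix(stats::rnorm(d * G, sd = 1.5), nrow = d, ncol = G)
    baseline <- stats::runif(G, min = 2, max = 6)
    profiles <- sweep(emb %*% loading, 2L, baseline, `+`)

    sim <- tcrossprod(emb)          # embedding dot products
    off <- !diag(TRUE, n)
    z <- sim
    z[off] <- (sim[off] - mean(sim[off])) / stats::sd(sim[off])

    eps <- matrix(stats::rnorm(n * n, sd = .PAIR_NOISE_SD), n, n)
    score <- config$effect_size * z + eps

    conn <- matrix(NA_real_, n, n)
    sc_off <- score[off]
    k <- round(config$frac_unconnected * length(sc_off))
    zero_mask <- rank(sc_off, ties.method = "first") <= k
    vals <- .CONN_SCALE * exp(sc_off)
    vals[zero_mask] <- 0
    conn[off] <- vals

    rownames(emb) <- rownames(profiles) <- seq_len(n)
    dimnames(conn) <- list(source = seq_len(n), target = seq_len(n))

    structure(
      list(region_embeddings = emb,
           region_mean_profiles = profiles,
           pair_connectivity = conn,
           gene_baseline = baseline,
           config = config),
      class = "ground_truth")
  })
}

#' Connectivity of one ordered region pair from a ground truth
#'
#' @param truth a [generate_ground_truth()] result.
#' @param source,target region IDs.
#' @return the planted connectivity value (non-negative), `NA` for
#'   `source == target`.
#' @export
pair_connectivity <- function(truth, source, target) {
  stopifnot(inherits(truth, "ground_truth"))
  truth$pair_connectivity[cbind(source, target)]
}

# Near-cubic factorization of the grid into >= n_regions axis-aligned blocks:
# greedily split the axis whose blocks are currently longest.
.block_splits <- function(dims, n_regions) {
  k <- c(1L, 1L, 1L)
  while (prod(k) < n_regions) {
    ratio <- dims / k
    ratio[k >= dims] <- -Inf
    i <- which.max(ratio)
    if (!is.finite(ratio[i])) {
      stop("grid too small to partition into that many regions", call. = FALSE)
    }
    k[i] <- k[i] + 1L
  }
  k
}

#' Generate coarse and fine annotation volumes
#'
#' Partitions the coarse grid into `n_regions` contiguous axis-aligned blocks
#' labeled `1..n_regions` (blocks beyond `n_regions` become background `0`),
#' then upsamples by exactly 2x per axis so each coarse voxel corresponds to
#' 8 fine voxels of the same region — mirroring the 200 um expression vs
#' 100 um projection resolutions.
#'
#' Volumes are linearized with the first (x) index fastest, i.e. R's native
#' array order.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `coarse` and `fine`, each an
#'   [annotation_volume()].
#' @export
generate_annotation_volume <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dims <- config$grid_dims_expr
  k <- .block_splits(dims, config$n_regions)

  # cut each axis into k[i] near-equal contiguous intervals
  axis_bins <- lapply(1:3, function(i) {
    if (k[i] == 1L) rep(1L, dims[i])
    else as.integer(cut(seq_len(dims[i]), breaks = k[i], labels = FALSE))
  })
  block_of <- array(0L, dim = dims)
  bx <- axis_bins[[1]]; by <- axis_bins[[2]]; bz <- axis_bins[[3]]
  # block raster index, x-blocks fastest
  block_idx <- outer(outer(bx - 1L, (by - 1L) * k[1], `+`),
                     (bz - 1L) * k[1] * k[2], `+`) + 1L
  block_of[] <- block_idx
  region <- ifelse(block_of <= config$n_regions, block_of, 0L)

  coarse <- annotation_volume(as.integer(region), dims, resolution_um = 200L)

  arr <- array(as.integer(region), dim = dims)
  fine_arr <- arr[rep(seq_len(dims[1]), each = 2L),
                  rep(seq_len(dims[2]), each = 2L),
                  rep(seq_len(dims[3]), each = 2L)]
  fine <- annotation_volume(as.integer(fine_arr), 2L * dims,
                            resolution_um = 100L)
  list(coarse = coarse, fine = fine)
}

#' Structure graph for a synthetic atlas
#'
#' A flat tree: one root (ID 1000) whose children are the region IDs
#' `1..n_regions`, matching the annotation volumes produced by
#' [generate_annotation_volume()].
#'
#' @param config a [synthetic_config()].
#' @return a [structure_graph()].
#' @export
synthetic_structure_graph <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_regions
  structure_graph(data.frame(
    id = c(1000L, seq_len(n)),
    acronym = c("root", sprintf("R%02d", seq_len(n))),
    parent = c(NA_integer_, rep(1000L, n))))
}

#' Generate the gene expression matrix over the coarse grid
#'
#' Every voxel of region `r` expresses gene `g` at
#' `max(0, region_mean_profiles[r, g] + N(0, noise_sd))`; background voxels
#' are all-zero columns.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param annot the coarse [annotation_volume()].
#' @param config the generating [synthetic_config()].
#' @return an [expression_matrix()] of shape `n_genes x n_voxels`.
#' @export
generate_expression_grids <- function(truth, annot, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(annot, "annotation_volume"),
            inherits(config, "synthetic_config"))
  if (annot$resolution_um != 200L) {
    stop("`annot` must be the coarse (200 um) annotation volume",
         call. = FALSE)
  }
  G <- config$n_genes
  V <- length(annot$region_of_voxel)
  region <- annot$region_of_voxel

  with_seed(config$seed + 1L, {
    values <- matrix(0, nrow = G, ncol = V)
    fg <- which(region > 0L)
    mu <- t(truth$region_mean_profiles)[, region[fg], drop = FALSE]  # G x |fg|
    if (config$noise_sd > 0) {
      mu <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                        nrow = G)
    }
    values[, fg] <- pmax(mu, 0)
    expression_matrix(values, gene_ids = seq_len(G))
  })
}

#' Generate tracer-injection experiments over the fine grid
#'
#' For each source region, `n_injections_per_source` experiments. Each
#' experiment draws one multiplicative factor from `U(1 - jitter, 1]` and
#' fills every fine voxel of each connected target region with
#' `max(0, factor * pair_connectivity(s, t) + N(0, proj_noise_sd))`; voxels
#' of unconnected targets (and everything else) stay zero. Because the
#' factor never exceeds 1, the per-experiment median under-reports the
#' planted value and the max across experiments is the consistent estimate —
#' the rationale for the median-then-max aggregation rule.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param annot_fine the fine [annotation_volume()].
#' @param config the generating [synthetic_config()].
#' @return list of [injection_experiment()] objects, sources in region order.
#' @export
generate_injection_experiments <- function(truth, annot_fine, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(annot_fine, "annotation_volume"),
            inherits(config, "synthetic_config"))
  if (annot_fine$resolution_um != 100L) {
    stop("`annot_fine` must be the fine (100 um) annotation volume",
         call. = FALSE)
  }
  n <- config$n_regions
  region <- annot_fine$region_of_voxel
  voxels_of <- split(seq_along(region), region)

  with_seed(config$seed + 2L, {
    out <- vector("list", n * config$n_injections_per_source)
    id <- 0L
    for (s in seq_len(n)) {
      for (e in seq_len(config$n_injections_per_source)) {
        id <- id + 1L
        factor_e <- 1 - stats::runif(1L, 0, config$jitter)
        proj <- numeric(length(region))
        for (t in seq_len(n)) {
          if (t == s) next
          cval <- truth$pair_connectivity[s, t]
          if (is.na(cval) || cval == 0) next
          vox <- voxels_of[[as.character(t)]]
          x <- rep(factor_e * cval, length(vox))
          if (config$proj_noise_sd > 0) {
            x <- x + stats::rnorm(length(vox), sd = config$proj_noise_sd)
          }
          proj[vox] <- pmax(x, 0)
        }
        out[[id]] <- injection_experiment(
          experiment_id = id, source_region = s, projection = proj,
          dims = annot_fine$dims, resolution_um = 100L)
      }
    }
    out
  })
}

#' Generate a complete synthetic atlas
#'
#' Convenience wrapper running ground truth, annotation volumes, structure
#' graph, expression grids and injection experiments in one deterministic
#' pass.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `truth`, `annotation` (list `coarse`/`fine`),
#'   `graph`, `expression`, `experiments`, `config`.
#' @export
generate_atlas <- function(config = synthetic_config()) {
  truth <- generate_ground_truth(config)
  annot <- generate_annotation_volume(config)
  graph <- synthetic_structure_graph(config)
  expr <- generate_expression_grids(truth, annot$coarse, config)
  exps <- generate_injection_experiments(truth, annot$fine, config)
  list(truth = truth, annotation = annot, graph = graph,
       expression = expr, experiments = exps, config = config)
}
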
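# From labeled region pairs + the expression matrix to normalized
# Source-Target vector datasets with per-class caps and a stratified
# train/validation/test split.

#' Source-Target vector dataset
#'
#' `features` is a `P x 2G` matrix — for each row, the first `G` columns are
#' the Source voxel's expression profile and the last `G` the Target
#' voxel's. `meta` carries one row per vector: `source_region`,
#' `target_region`, `source_voxel`, `target_voxel` (0-based voxel IDs) and
#' `label`.
#'
#' @param features numeric matrix, `P x 2G`.
#' @param meta data.frame with `P` rows.
#' @return an object of class `st_dataset`.
#' @export
st_dataset <- function(features, meta) {
  stopifnot(is.matrix(features), is.data.frame(meta),
            nrow(features) == nrow(meta))
  needed <- c("source_region", "target_region", "source_voxel",
              "target_voxel", "label")
  if (!all(needed %in% names(meta))) {
    stop("`meta` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  rownames(meta) <- NULL
  structure(list(features = features, meta = meta), class = "st_dataset")
}

#' @export
dim.st_dataset <- function(x) dim(x$features)

#' Subset an st_dataset by row index
#' @param ds an [st_dataset()].
#' @param i row indices.
#' @return an [st_dataset()] with the selected rows.
#' @export
subset_dataset <- function(ds, i) {
  st_dataset(ds$features[i, , drop = FALSE], ds$meta[i, , drop = FALSE])
}

#' Bind datasets rowwise
#' @param ... [st_dataset()] objects with matching feature width.
#' @return the concatenated [st_dataset()].
#' @export
rbind_datasets <- function(...) {
  parts <- list(...)
  st_dataset(do.call(rbind, lapply(parts, `[[`, "features")),
             do.call(rbind, lapply(parts, `[[`, "meta")))
}

#' Dataset build configuration
#'
#' @param M voxels sampled per region per pair (the study uses 21).
#' @param per_class_cap named numeric vector mapping class label
#'   (as character, e.g. `"0"`) to the maximum number of vectors kept;
#'   `Inf` = keep all. Must cover every label present when applied.
#' @param pairing_mode `"index_paired"` (M vectors per pair: i-th source
#'   voxel with i-th target voxel) or `"cross_product"` (M^2 vectors).
#' @param fractions named train/validation/test fractions summing to 1.
#' @param normalize_on `"train"` (fit the min-max scaler on the training
#'   partition only) or `"all"` (fit on the full dataset).
#' @param seed integer seed driving voxel selection, caps and the split.
#' @return an object of class `build_config`.
#' @export
build_config <- function(M = 21L,
                         per_class_cap = c("0" = 5000, "1" = 5000,
                                           "2" = Inf),
                         pairing_mode = c("index_paired", "cross_product"),
                         fractions = c(train = 0.72, validation = 0.08,
                                       test = 0.20),
                         normalize_on = c("train", "all"),
                         seed = 1L) {
  M <- stopifnot_count(M, "M")
  pairing_mode <- match.arg(pairing_mode)
  normalize_on <- match.arg(normalize_on)
  if (any(per_class_cap < 0)) stop("caps must be >= 0", call. = FALSE)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three positive numbers summing to 1",
         call. = FALSE)
  }
  names(fractions) <- c("train", "validation", "test")
  seed <- stopifnot_count(seed, "seed", min = 0L)
  structure(list(M = M, per_class_cap = per_class_cap,
                 pairing_mode = pairing_mode, fractions = fractions,
                 normalize_on = normalize_on, seed = seed),
            class = "build_config")
}

#' Sample M voxels of a region, eligible-expression only
#'
#' Eligible voxels are those annotated to `region` whose expression column
#' is not all-zero (all-zero columns are exactly the rows dropped by the
#' database zero-filter). Sampling is uniform without replacement when at
#' least `M` eligible voxels exist; otherwise with replacement, with a
#' warning.
#'
#' @param region region ID.
#' @param annot the coarse [annotation_volume()].
#' @param expr the [expression_matrix()].
#' @param M number of voxels.
#' @param seed integer seed; the same seed always returns the same voxels.
#' @return integer vector of `M` 0-based voxel IDs.
#' @export
select_region_voxels <- function(region, annot, expr, M, seed) {
  stopifnot(inherits(annot, "annotation_volume"),
            inherits(expr, "expression_matrix"))
  in_region <- which(annot$region_of_voxel == region)
  eligible <- in_region[colSums(expr$values[, in_region, drop = FALSE]) > 0]
  if (length(eligible) == 0L) {
    stop(sprintf("empty region: region %d has no voxels with nonzero expression",
                 region), call. = FALSE)
  }
  with_seed(seed, {
    if (length(eligible) >= M) {
      sample_from(eligible, M) - 1L
    } else {
      warning(sprintf(
        "region %d has only %d eligible voxels; sampling %d with replacement",
        region, length(eligible), M), call. = FALSE)
      sample_from(eligible, M, replace = TRUE) - 1L
    }
  })
}

#' Build the Source-Target vectors of one region pair
#'
#' Each vector is the Source voxel's G-length expression profile followed by
#' the Target voxel's (`a || b`); swapping source and target yields `b || a`.
#'
#' @param source_region,target_region region IDs (metadata only).
#' @param src_voxels,tgt_voxels 0-based voxel IDs of length `M`.
#' @param expr the [expression_matrix()].
#' @param label the pair's class label.
#' @param mode `"index_paired"` (M vectors) or `"cross_product"`
#'   (M^2 vectors).
#' @return an [st_dataset()].
#' @export
build_pair_vectors <- function(source_region, target_region,
                               src_voxels, tgt_voxels, expr, label,
                               mode = c("index_paired", "cross_product")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expression_matrix"),
            length(src_voxels) == length(tgt_voxels))
  V <- expr$voxel_count
  if (any(src_voxels < 0 | src_voxels >= V) ||
      any(tgt_voxels < 0 | tgt_voxels >= V)) {
    stop("consistency error: voxel ID outside the expression matrix",
         call. = FALSE)
  }
  if (mode == "cross_product") {
    grid <- expand.grid(s = src_voxels, t = tgt_voxels)
    src_voxels <- grid$s
    tgt_voxels <- grid$t
  }
  features <- cbind(t(expr$values[, src_voxels + 1L, drop = FALSE]),
                    t(expr$values[, tgt_voxels + 1L, drop = FALSE]))
  dimnames(features) <- NULL
  st_dataset(features, data.frame(
    source_region = source_region, target_region = target_region,
    source_voxel = src_voxels, target_voxel = tgt_voxels,
    label = label))
}

#' Subsample each class down to its cap
#'
#' @param ds an [st_dataset()].
#' @param caps named vector mapping label (as character) to the maximum
#'   number of vectors retained; must cover every label present. A cap of 0
#'   removes the class; `Inf` keeps everything.
#' @param seed integer seed.
#' @return the capped [st_dataset()] (original row order preserved).
#' @export
apply_class_caps <- function(ds, caps, seed) {
  stopifnot(inherits(ds, "st_dataset"))
  labels <- as.character(ds$meta$label)
  present <- unique(labels)
  uncapped <- setdiff(present, names(caps))
  if (length(uncapped)) {
    stop("no cap defined for label(s): ", paste(uncapped, collapse = ", "),
         call. = FALSE)
  }
  keep <- with_seed(seed, {
    unlist(lapply(present, function(lab) {
      idx <- which(labels == lab)
      cap <- caps[[lab]]
      if (length(idx) <= cap) idx else sample_from(idx, cap)
    }), use.names = FALSE)
  })
  subset_dataset(ds, sort(keep))
}

#' Stratified train/validation/test split
#'
#' Overall sizes follow the rounding rule `test = round(f_test * n)`,
#' `validation = round(f_val * n)`, `train = remainder`; within each split
#' the per-class allocation uses largest-remainder rounding of the
#' stratified quota, so the three parts are disjoint, exhaustive, hit the
#' overall sizes exactly, and each class is within one vector of its
#' stratified expectation.
#'
#' With `by_pair = TRUE` the unit of allocation is the (source, target)
#' region pair instead of the vector: all vectors of a pair land in the same
#' partition, so test performance measures generalization to unseen pairs.
#' Sizes then match the fractions only approximately (pair granularity).
#'
#' @param ds an [st_dataset()].
#' @param fractions named positive fractions `(train, validation, test)`
#'   summing to 1.
#' @param seed integer seed.
#' @param by_pair split at region-pair granularity (default `FALSE`:
#'   vector-level, the protocol used for the headline tasks).
#' @return an object of class `dataset_split`: list with `train`,
#'   `validation`, `test` ([st_dataset()]s), plus `fractions` and `seed`.
#' @export
split_dataset <- function(ds,
                          fractions = c(train = 0.72, validation = 0.08,
                                        test = 0.20),
                          seed = 1L, by_pair = FALSE) {
  stopifnot(inherits(ds, "st_dataset"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three positive numbers summing to 1",
         call. = FALSE)
  }
  names(fractions) <- c("train", "validation", "test")
  n <- nrow(ds$features)
  if (by_pair) {
    return(.split_by_pair(ds, fractions, seed))
  }

  labels <- as.character(ds$meta$label)
  classes <- sort(unique(labels))
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  n_by_class <- lengths(idx_by_class)

  n_test <- round(fractions[["test"]] * n)
  n_val <- round(fractions[["validation"]] * n)
  if (n_test + n_val >= n) stop("split error: no training data left",
                                call. = FALSE)

  # largest-remainder allocation of `total` across classes with quota
  # proportional to weights, capped by `avail`
  allocate <- function(total, weights, avail) {
    quota <- total * weights / sum(weights)
    base <- pmin(floor(quota), avail)
    rem <- total - sum(base)
    frac <- quota - floor(quota)
    ord <- order(frac, decreasing = TRUE)
    take <- base
    for (i in ord) {
      if (rem == 0) break
      if (take[i] < avail[i]) {
        take[i] <- take[i] + 1L
        rem <- rem - 1L
      }
    }
    if (rem > 0) {  # spill over wherever room remains
      for (i in order(avail - take, decreasing = TRUE)) {
        add <- min(rem, avail[i] - take[i])
        take[i] <- take[i] + add
        rem <- rem - add
        if (rem == 0) break
      }
    }
    as.integer(take)
  }

  test_alloc <- allocate(n_test, n_by_class, n_by_class)
  val_alloc <- allocate(n_val, n_by_class, n_by_class - test_alloc)

  with_seed(seed, {
    test_idx <- integer(0); val_idx <- integer(0); train_idx <- integer(0)
    for (k in seq_along(classes)) {
      idx <- sample_from(idx_by_class[[k]], n_by_class[k])  # permute
      t_k <- test_alloc[k]; v_k <- val_alloc[k]
      test_idx <- c(test_idx, idx[seq_len(t_k)])
      val_idx <- c(val_idx, idx[seq_len(v_k) + t_k])
      train_idx <- c(train_idx, idx[seq(t_k + v_k + 1L,
                                        length.out = n_by_class[k] - t_k - v_k)])
    }
    if (length(train_idx) == 0L || length(val_idx) == 0L ||
        length(test_idx) == 0L) {
      stop("split error: a partition is empty", call. = FALSE)
    }
    structure(list(train = subset_dataset(ds, sort(train_idx)),
                   validation = subset_dataset(ds, sort(val_idx)),
                   test = subset_dataset(ds, sort(test_idx)),
                   fractions = fractions, seed = seed, by_pair = FALSE),
              class = "dataset_split")
  })
}

# pair-granular stratified split: permute each class's pairs, then fill
# test, validation, train in that order until each reaches its share of the
# class's vectors.
.split_by_pair <- function(ds, fractions, seed) {
  pair_key <- paste(ds$meta$source_region, ds$meta$target_region, sep = "->")
  pair_label <- tapply(as.character(ds$meta$label), pair_key,
                       function(x) x[1])
  pair_size <- table(pair_key)
  with_seed(seed, {
    part_of <- character(0)
    for (cl in sort(unique(pair_label))) {
      pairs <- names(pair_label)[pair_label == cl]
      pairs <- sample_from(pairs, length(pairs))
      n_cl <- sum(pair_size[pairs])
      target <- c(test = fractions[["test"]] * n_cl,
                  validation = fractions[["validation"]] * n_cl)
      got <- c(test = 0, validation = 0)
      for (p in pairs) {
        dest <- if (got[["test"]] < target[["test"]]) "test"
        else if (got[["validation"]] < target[["validation"]]) "validation"
        else "train"
        part_of[p] <- dest
        if (dest != "train") got[[dest]] <- got[[dest]] + pair_size[[p]]
      }
    }
    parts <- lapply(c(train = "train", validation = "validation",
                      test = "test"), function(nm) {
      subset_dataset(ds, which(part_of[pair_key] == nm))
    })
    if (any(vapply(parts, function(p) nrow(p$features), integer(1)) == 0L)) {
      stop("split error: a partition is empty (too few pairs per class)",
           call. = FALSE)
    }
    structure(c(parts, list(fractions = fractions, seed = seed,
                            by_pair = TRUE)),
              class = "dataset_split")
  })
}

#' Fit and apply per-feature min-max scaling
#'
#' The scaler (per-feature min and range) is estimated on the training
#' partition only, then the same affine map is applied to validation and
#' test; features constant on train map to 0, and out-of-range values in
#' the non-training partitions are clipped to `[0, 1]`. Set
#' `fit_on = "all"` to fit on the union instead (strict-replication mode;
#' leaks test statistics into the scaler).
#'
#' @param split a [split_dataset()] result.
#' @param fit_on `"train"` or `"all"`.
#' @return list with `split` (normalized) and `scaler`
#'   (list `min`, `range`).
#' @export
normalize_split <- function(split, fit_on = c("train", "all")) {
  fit_on <- match.arg(fit_on)
  stopifnot(inherits(split, "dataset_split"))
  ref <- if (fit_on == "train") split$train$features else {
    rbind(split$train$features, split$validation$features,
          split$test$features)
  }
  fmin <- apply(ref, 2L, min)
  frange <- apply(ref, 2L, max) - fmin
  scaler <- list(min = fmin, range = frange)
  for (part in c("train", "validation", "test")) {
    split[[part]]$features <- apply_scaler(split[[part]]$features, scaler)
  }
  list(split = split, scaler = scaler)
}

#' Apply a fitted min-max scaler
#'
#' @param features numeric matrix.
#' @param scaler list with `min` and `range` as returned by
#'   [normalize_split()].
#' @return scaled matrix, every entry in `[0, 1]`; constant features map
#'   to 0.
#' @export
apply_scaler <- function(features, scaler) {
  rng <- ifelse(scaler$range == 0, 1, scaler$range)
  out <- sweep(sweep(features, 2L, scaler$min, `-`), 2L, rng, `/`)
  out[, scaler$range == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Build a complete Source-Target dataset from labeled pairs
#'
#' For every labeled, non-excluded ordered region pair: sample `M` source
#' and `M` target voxels ([select_region_voxels()]; per-pair seeds derived
#' from `config$seed`), build the concatenated vectors, pool, apply
#' per-class caps, split, and normalize. Self-pairs are never built.
#'
#' @param pairs data.frame from [pair_connectivity_table()] with a `label`
#'   column (`NA` rows are excluded).
#' @param annot the coarse [annotation_volume()].
#' @param expr the [expression_matrix()].
#' @param config a [build_config()].
#' @param by_pair passed to [split_dataset()].
#' @return list with `split` (normalized [split_dataset()]), `scaler`,
#'   `dataset` (capped, pre-split), and `log` (pair/vector counts).
#' @export
build_st_dataset <- function(pairs, annot, expr, config = build_config(),
                             by_pair = FALSE) {
  stopifnot(is.data.frame(pairs), inherits(config, "build_config"))
  if (!"label" %in% names(pairs)) {
    stop("`pairs` must carry a `label` column (see pair_connectivity_table)",
         call. = FALSE)
  }
  usable <- pairs[!is.na(pairs$label) &
                    pairs$source_region != pairs$target_region, ,
                  drop = FALSE]
  if (nrow(usable) == 0L) stop("no usable labeled pairs", call. = FALSE)

  parts <- vector("list", nrow(usable))
  for (i in seq_len(nrow(usable))) {
    s <- usable$source_region[i]
    t <- usable$target_region[i]
    src <- select_region_voxels(s, annot, expr, config$M,
                                seed = config$seed + 2L * i)
    tgt <- select_region_voxels(t, annot, expr, config$M,
                                seed = config$seed + 2L * i + 1L)
    parts[[i]] <- build_pair_vectors(s, t, src, tgt, expr,
                                     label = usable$label[i],
                                     mode = config$pairing_mode)
  }
  full <- do.call(rbind_datasets, parts)
  capped <- apply_class_caps(full, config$per_class_cap,
                             seed = config$seed + 10000L)
  split <- split_dataset(capped, config$fractions,
                         seed = config$seed + 20000L, by_pair = by_pair)
  norm <- normalize_split(split, fit_on = config$normalize_on)

  log <- list(n_pairs = nrow(usable),
              n_vectors_built = nrow(full$features),
              n_vectors_after_caps = nrow(capped$features),
              class_sizes = table(capped$meta$label),
              split_sizes = vapply(norm$split[c("train", "validation",
                                                "test")],
                                   function(p) nrow(p$features), integer(1)))
  list(split = norm$split, scaler = norm$scaler, dataset = capped,
       log = log)
}

#' Export a dataset as CSV plus a JSON manifest
#'
#' One CSV row per vector: IDs, label, then the features; the manifest
#' records G, M, caps, seed, fractions and the scaler so the dataset can be
#' rebuilt or audited.
#'
#' @param built a [build_st_dataset()] result.
#' @param config the [build_config()] used.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(built, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (part in c("train", "validation", "test")) {
    ds <- built$split[[part]]
    df <- cbind(ds$meta, as.data.frame(ds$features))
    names(df) <- c(names(ds$meta),
                   sprintf("f%d", seq_len(ncol(ds$features)) - 1L))
    utils::write.csv(df, file.path(dir, paste0(part, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(G = ncol(built$split$train$features) / 2,
         M = config$M,
         per_class_cap = as.list(config$per_class_cap),
         pairing_mode = config$pairing_mode,
         fractions = as.list(config$fractions),
         seed = config$seed,
         scaler = list(min = built$scaler$min, range = built$scaler$range),
         split_sizes = as.list(built$log$split_sizes)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
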
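# Source-Target vector construction, caps, normalization, splits.

test_that("select_region_voxels samples eligible voxels deterministically", {
  atlas <- small_atlas()
  annot <- atlas$annotation$coarse
  expr <- atlas$expression
  v1 <- select_region_voxels(1L, annot, expr, M = 10L, seed = 7L)
  v2 <- select_region_voxels(1L, annot, expr, M = 10L, seed = 7L)
  expect_identical(v1, v2)
  expect_length(v1, 10L)
  expect_true(all(annot$region_of_voxel[v1 + 1L] == 1L))
  expect_length(unique(v1), 10L)  # without replacement

  v3 <- select_region_voxels(1L, annot, expr, M = 10L, seed = 8L)
  expect_false(identical(v1, v3))
})

test_that("scarce regions trigger replacement sampling with a warning; empty regions error", {
  expr <- toy_expression(G = 3L, V = 8L)
  annot <- annotation_volume(c(1L, 1L, 1L, 2L, 0L, 0L, 0L, 0L),
                             c(8L, 1L, 1L), 200L)
  # region with exactly M eligible voxels: forced selection
  forced <- select_region_voxels(1L, annot, expr, M = 3L, seed = 1L)
  expect_setequal(forced, 0:2)
  # M-1 eligible: with replacement + warning, at least one repeat
  expect_warning(
    over <- select_region_voxels(1L, annot, expr, M = 4L, seed = 1L),
    "with replacement")
  expect_lt(length(unique(over)), 4L)
  # zero-expression voxels are ineligible
  expr0 <- expr
  expr0$values[, 4L] <- 0
  expect_error(select_region_voxels(2L, annot, expr0, M = 1L, seed = 1L),
               "empty region")
})

test_that("pair vectors concatenate source then target profiles", {
  expr <- toy_expression(G = 4L, V = 6L)
  ds <- build_pair_vectors(1L, 2L, src_voxels = c(0L, 1L),
                           tgt_voxels = c(2L, 3L), expr, label = 1L,
                           mode = "index_paired")
  expect_equal(dim(ds$features), c(2L, 8L))
  expect_equal(ds$features[1, ], unname(c(expr$values[, 1], expr$values[, 3])))
  # swapping source and target reverses the halves
  sw <- build_pair_vectors(2L, 1L, src_voxels = c(2L, 3L),
                           tgt_voxels = c(0L, 1L), expr, label = 1L)
  expect_equal(sw$features[1, ], unname(c(expr$values[, 3], expr$values[, 1])))
  expect_false(identical(ds$features[1, ], sw$features[1, ]))

  cross <- build_pair_vectors(1L, 2L, c(0L, 1L), c(2L, 3L), expr,
                              label = 0L, mode = "cross_product")
  expect_equal(nrow(cross$features), 4L)

  expect_error(build_pair_vectors(1L, 2L, c(0L, 99L), c(2L, 3L), expr, 1L),
               "consistency error")
})

test_that("class caps subsample deterministically and can drop a class", {
  ds <- st_dataset(matrix(runif(600 * 2), 600),
                   data.frame(source_region = 1L, target_region = 2L,
                              source_voxel = 0L, target_voxel = 1L,
                              label = rep(c(0L, 1L, 2L), c(300, 200, 100))))
  capped <- apply_class_caps(ds, c("0" = 150, "1" = 500, "2" = Inf),
                             seed = 3L)
  expect_equal(as.integer(table(capped$meta$label)), c(150L, 200L, 100L))
  capped2 <- apply_class_caps(ds, c("0" = 150, "1" = 500, "2" = Inf),
                              seed = 3L)
  expect_identical(capped, capped2)
  dropped <- apply_class_caps(ds, c("0" = 0, "1" = Inf, "2" = Inf),
                              seed = 3L)
  expect_false(any(dropped$meta$label == 0L))
  expect_error(apply_class_caps(ds, c("0" = 10), seed = 1L), "no cap")
})

test_that("min-max normalization fits on train only, clips, zeroes constants", {
  tr <- st_dataset(matrix(c(2, 4, 3,  5, 5, 5), ncol = 2),
                   data.frame(source_region = 1L, target_region = 2L,
                              source_voxel = 0L, target_voxel = 1L,
                              label = c(0L, 1L, 0L)))
  te <- st_dataset(matrix(c(3, 5, 1,  4, 6, 5), ncol = 2),
                   data.frame(source_region = 1L, target_region = 2L,
                              source_voxel = 0L, target_voxel = 1L,
                              label = c(0L, 1L, 1L)))
  split <- structure(list(train = tr, validation = te, test = te,
                          fractions = c(train = .5, validation = .25,
                                        test = .25),
                          seed = 1L, by_pair = FALSE),
                     class = "dataset_split")
  norm <- normalize_split(split)
  # train feature spanning [2,4]: 3 -> 0.5; constant column -> 0
  expect_equal(norm$split$train$features[, 1], c(0, 1, 0.5))
  expect_equal(norm$split$train$features[, 2], c(0, 0, 0))
  # test value 5 on range [2,4] clips to 1; 1 clips to 0
  expect_equal(norm$split$test$features[, 1], c(0.5, 1, 0))
  expect_true(all(norm$split$test$features >= 0 &
                    norm$split$test$features <= 1))
  # scaler depends on train alone: perturbing test leaves it unchanged
  split2 <- split
  split2$test$features[1, 1] <- 100
  expect_identical(normalize_split(split2)$scaler, norm$scaler)
})

test_that("stratified split hits exact overall sizes and conserves vectors", {
  make_ds <- function(labels) {
    n <- length(labels)
    st_dataset(matrix(runif(n), ncol = 1),
               data.frame(source_region = 1L, target_region = 2L,
                          source_voxel = 0L, target_voxel = 1L,
                          label = labels))
  }
  ds100 <- make_ds(rep(c(0L, 1L), c(60, 40)))
  sp <- split_dataset(ds100, c(0.72, 0.08, 0.20), seed = 1L)
  sizes <- vapply(sp[c("train", "validation", "test")],
                  function(p) nrow(p$features), integer(1))
  expect_equal(unname(sizes), c(72L, 8L, 20L))

  # conservation and disjointness across several n and fractions
  set.seed(42)
  for (n in c(17, 100, 731)) {
    labels <- sample(0:2, n, replace = TRUE)
    ds <- make_ds(labels)
    fr <- c(0.6, 0.15, 0.25)
    sp <- split_dataset(ds, fr, seed = 2L)
    ns <- vapply(sp[c("train", "validation", "test")],
                 function(p) nrow(p$features), integer(1))
    expect_equal(sum(ns), n)
    expect_equal(unname(ns[["test"]]), round(0.25 * n))
    expect_equal(unname(ns[["validation"]]), round(0.15 * n))
    # stratification within 2 of expectation per class per part
    for (part in c("train", "validation", "test")) {
      got <- table(factor(sp[[part]]$meta$label, levels = 0:2))
      want <- table(factor(labels, levels = 0:2)) * fr[[
        c(train = 1, validation = 2, test = 3)[[part]]]]
      expect_true(all(abs(got - want) <= 2))
    }
  }

  sp_a <- split_dataset(ds100, seed = 9L)
  sp_b <- split_dataset(ds100, seed = 9L)
  expect_identical(sp_a, sp_b)
})

test_that("pair-disjoint split keeps all vectors of a pair together", {
  atlas <- small_atlas()
  pairs <- pair_connectivity_table(atlas$experiments,
                                   atlas$annotation$fine,
                                   scheme = label_scheme("binary"))
  built <- build_st_dataset(pairs, atlas$annotation$coarse,
                            atlas$expression,
                            build_config(M = 5L,
                                         per_class_cap = c("0" = Inf,
                                                           "1" = Inf)),
                            by_pair = TRUE)
  key <- function(ds) unique(paste(ds$meta$source_region,
                                   ds$meta$target_region))
  k_tr <- key(built$split$train)
  k_va <- key(built$split$validation)
  k_te <- key(built$split$test)
  expect_length(intersect(k_tr, k_te), 0L)
  expect_length(intersect(k_tr, k_va), 0L)
  expect_length(intersect(k_va, k_te), 0L)
})

test_that("build_st_dataset is deterministic end to end and zeroing a target zeroes the right half", {
  atlas <- small_atlas()
  pairs <- pair_connectivity_table(atlas$experiments,
                                   atlas$annotation$fine,
                                   scheme = label_scheme("binary"))
  bc <- build_config(M = 4L, per_class_cap = c("0" = Inf, "1" = Inf),
                     seed = 5L)
  b1 <- build_st_dataset(pairs, atlas$annotation$coarse, atlas$expression,
                         bc)
  b2 <- build_st_dataset(pairs, atlas$annotation$coarse, atlas$expression,
                         bc)
  expect_identical(b1$split, b2$split)

  # zero the expression of one target region -> exactly the second half of
  # that pair's (un-normalized) vectors is zero
  expr0 <- atlas$expression
  tgt <- b1$dataset$meta$target_region[1]
  expr0$values[, atlas$annotation$coarse$region_of_voxel == tgt] <- 0
  G <- length(atlas$expression$gene_ids)
  v <- select_region_voxels(b1$dataset$meta$source_region[1],
                            atlas$annotation$coarse, atlas$expression,
                            2L, seed = 1L)
  w_ok <- select_region_voxels(tgt, atlas$annotation$coarse,
                               atlas$expression, 2L, seed = 1L)
  vec <- build_pair_vectors(1L, tgt, v, w_ok, expr0, label = 1L)
  expect_true(all(vec$features[, (G + 1):(2 * G)] == 0))
  expect_true(any(vec$features[, 1:G] != 0))
})

test_that("dataset CSV export round-trips through the reader", {
  atlas <- small_atlas()
  pairs <- pair_connectivity_table(atlas$experiments,
                                   atlas$annotation$fine,
                                   scheme = label_scheme("binary"))
  bc <- build_config(M = 3L, per_class_cap = c("0" = Inf, "1" = Inf),
                     seed = 2L)
  built <- build_st_dataset(pairs, atlas$annotation$coarse,
                            atlas$expression, bc)
  dir <- withr::local_tempdir()
  write_dataset_csv(built, bc, dir)
  back <- voxconn:::read_dataset_dir(dir)
  expect_equal(back$split$train$features, built$split$train$features,
               tolerance = 1e-12)
  expect_equal(back$split$test$meta$label, built$split$test$meta$label)
  expect_equal(back$manifest$G, length(atlas$expression$gene_ids))
})
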
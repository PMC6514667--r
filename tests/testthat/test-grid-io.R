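# File formats: raw float32 volumes, NRRD, CSV, structure graph JSON,
# annotation harmonization, SQLite store.

test_that("raw expression volumes round-trip bit-exactly at float32", {
  dims <- c(5L, 4L, 3L)
  # multiples of 1/256 are exactly representable in float32
  values <- sample(0:2048, prod(dims), replace = TRUE) / 256
  path <- withr::local_tempfile(fileext = ".raw")
  write_expression_volume(values, path, dims)
  expect_identical(read_expression_volume(path, dims), values)
  # sidecar header carries dims
  expect_identical(read_expression_volume(path), values)
})

test_that("malformed raw volumes raise a format error naming the counts", {
  dims <- c(4L, 4L, 4L)
  path <- withr::local_tempfile(fileext = ".raw")
  write_expression_volume(runif(prod(dims)), path, dims)
  con <- file(path, "ab")
  writeBin(raw(10), con)
  close(con)
  expect_error(read_expression_volume(path, dims), "expected 64 float32")
})

test_that("NRRD volumes round-trip, including all-zero and synthetic experiments", {
  path <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(numeric(512), path, c(8L, 8L, 8L))
  got <- read_nrrd(path)
  expect_identical(got$dims, c(8L, 8L, 8L))
  expect_identical(got$values, numeric(512))

  vals <- sample(0:4096, 60, replace = TRUE) / 512
  write_nrrd(vals, path, c(5L, 4L, 3L))
  expect_identical(read_nrrd(path)$values, vals)

  # a generated experiment survives write -> read unchanged
  atlas <- noiseless_atlas()
  exp1 <- atlas$experiments[[7]]
  dir <- withr::local_tempdir()
  p <- write_injection_nrrd(exp1, dir)
  back <- read_injection_nrrd(p)
  expect_equal(back$experiment_id, exp1$experiment_id)
  expect_equal(back$source_region, exp1$source_region)
  expect_equal(back$dims, exp1$dims)
  expect_equal(back$projection, exp1$projection, tolerance = 1e-6)
})

test_that("truncated NRRD payloads are rejected", {
  path <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(runif(27), path, c(3L, 3L, 3L))
  bytes <- readBin(path, "raw", file.size(path))
  writeBin(bytes[-length(bytes)], path)
  expect_error(read_nrrd(path), "NRRD format error")
})

test_that("expression and annotation CSVs round-trip", {
  expr <- toy_expression()
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_csv(expr, path)
  back <- read_expression_csv(path)
  expect_equal(back$values, expr$values)
  expect_equal(back$gene_ids, expr$gene_ids)

  annot <- small_atlas()$annotation$coarse
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(annot, path2)
  expect_identical(read_annotation_csv(path2), annot)
})

test_that("structure graph validates shape and round-trips through JSON", {
  good <- structure_graph(data.frame(id = c(10L, 1L, 2L),
                                     acronym = c("root", "A", "B"),
                                     parent = c(NA, 10L, 10L)))
  path <- withr::local_tempfile(fileext = ".json")
  write_structure_graph(good, path)
  expect_identical(read_structure_graph(path)$nodes, good$nodes)

  expect_error(structure_graph(data.frame(id = c(1L, 1L),
                                          acronym = c("a", "b"),
                                          parent = c(NA, 1L))),
               "duplicate")
  expect_error(structure_graph(data.frame(id = 1:2, acronym = c("a", "b"),
                                          parent = c(2L, 1L))),
               "root")
  expect_error(structure_graph(data.frame(id = 1:3,
                                          acronym = c("r", "a", "b"),
                                          parent = c(NA, 3L, 2L))),
               "cycle")
})

test_that("harmonize_annotation rolls labels up to the nearest target ancestor", {
  # chain: root(1) -> A(2) -> leaf(3); sibling branch root -> B(4)
  graph <- structure_graph(data.frame(
    id = c(1L, 2L, 3L, 4L),
    acronym = c("root", "A", "leaf", "B"),
    parent = c(NA, 1L, 2L, 1L)))
  annot <- annotation_volume(c(3L, 2L, 4L, 0L, 3L, 2L, 4L, 3L),
                             c(2L, 2L, 2L), 100L)

  # one-step roll-up: leaf -> A when A is a target; targets stay put
  h1 <- harmonize_annotation(annot, graph, c(2L, 4L))
  expect_identical(h1$region_of_voxel,
                   c(2L, 2L, 4L, 0L, 2L, 2L, 4L, 2L))

  # 3-level chain to root only: every labeled voxel maps to root
  h2 <- harmonize_annotation(annot, graph, 1L)
  expect_identical(h2$region_of_voxel,
                   c(1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L))

  # no ancestor in the target set -> background
  h3 <- harmonize_annotation(annot, graph, 4L)
  expect_identical(h3$region_of_voxel,
                   c(0L, 0L, 4L, 0L, 0L, 0L, 4L, 0L))

  # idempotence
  expect_identical(harmonize_annotation(h1, graph, c(2L, 4L)), h1)

  expect_error(harmonize_annotation(annot, graph, 99L), "not in graph")
})

test_that("SQLite store round-trips and zero-filters voxID2GenExpr", {
  atlas <- small_atlas()
  annot <- atlas$annotation$coarse
  expr <- atlas$expression
  medians <- injection_target_medians(atlas$experiments,
                                      atlas$annotation$fine)
  path <- withr::local_tempfile(fileext = ".sqlite")
  store_database(path, annot, expr, atlas$experiments,
                 medians[, c("injection_id", "median_value",
                             "target_region")])

  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  withr::defer(DBI::dbDisconnect(con))
  ge <- DBI::dbReadTable(con, "voxID2GenExpr")
  expect_equal(nrow(ge), sum(expr$values != 0))
  expect_true(all(ge$gene_expression_value != 0))

  back <- load_database(path)
  expect_identical(back$annotation, annot)
  expect_equal(back$expression$values, expr$values)
  expect_equal(back$pair_medians$median_value, medians$median_value)
  expect_equal(nrow(back$injections), length(atlas$experiments))
})

test_that("a specific zeroed expression entry vanishes from the table and reloads as 0", {
  expr <- toy_expression()
  expr$values[2L, 3L] <- 0
  annot <- annotation_volume(rep(1L, 6), c(6L, 1L, 1L), 200L)
  path <- withr::local_tempfile(fileext = ".sqlite")
  store_database(path, annot, expr, list(), NULL)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  withr::defer(DBI::dbDisconnect(con))
  ge <- DBI::dbReadTable(con, "voxID2GenExpr")
  expect_false(any(ge$gene_id == 2L & ge$voxel_id == 2L))
  back <- load_database(path)
  expect_identical(unname(back$expression$values[2L, 3L]), 0)
  expect_equal(nrow(back$injections), 0L)
  expect_equal(nrow(back$pair_medians), 0L)
})

test_that("loading a database with a broken schema fails loudly", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbWriteTable(con, "something_else", data.frame(x = 1))
  DBI::dbDisconnect(con)
  expect_error(load_database(path), "schema error")
})
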
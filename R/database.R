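# Four-table SQLite persistence of a processed atlas: spatial annotation,
# zero-filtered expression, injection sources, and per-target medians.

.SCHEMA_VERSION <- 1L
.REQUIRED_TABLES <- c("voxID2Annotation", "voxID2GenExpr",
                      "injection2regionID", "injection2target", "meta")

#' Store a processed atlas in an SQLite database
#'
#' Creates four relational tables plus a small `meta` table:
#' \describe{
#'   \item{voxID2Annotation}{0-based voxel ID and its structure annotation
#'     (coarse grid).}
#'   \item{voxID2GenExpr}{gene expression value, voxel ID, gene ID — rows
#'     with expression value exactly 0 are filtered out; they read back as
#'     zeros.}
#'   \item{injection2regionID}{injection ID and its source region ID.}
#'   \item{injection2target}{injection ID, median projection value over a
#'     target region, and that target's annotation ID.}
#'   \item{meta}{schema version, grid dims, resolution and gene IDs, so the
#'     in-memory objects can be reconstructed exactly.}
#' }
#'
#' @param path SQLite file path (overwritten).
#' @param annot coarse [annotation_volume()].
#' @param expr [expression_matrix()] aligned to `annot`.
#' @param experiments list of [injection_experiment()] (only IDs and source
#'   regions are stored; projection volumes live in their NRRD files).
#' @param pair_medians data.frame with columns `injection_id`,
#'   `median_value`, `target_region` (see [injection_target_medians()]).
#' @return `path`, invisibly.
#' @export
store_database <- function(path, annot, expr, experiments, pair_medians) {
  stopifnot(inherits(annot, "annotation_volume"),
            inherits(expr, "expression_matrix"))
  if (expr$voxel_count != length(annot$region_of_voxel)) {
    stop("expression matrix and annotation volume have different voxel counts",
         call. = FALSE)
  }
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))

  DBI::dbWriteTable(con, "voxID2Annotation", data.frame(
    voxel_id = seq_along(annot$region_of_voxel) - 1L,
    structure_annotation = annot$region_of_voxel))

  nz <- which(expr$values != 0, arr.ind = TRUE)
  DBI::dbWriteTable(con, "voxID2GenExpr", data.frame(
    gene_expression_value = expr$values[nz],
    voxel_id = nz[, "col"] - 1L,
    gene_id = expr$gene_ids[nz[, "row"]]))

  inj_df <- if (length(experiments)) {
    data.frame(
      injection_id = vapply(experiments, `[[`, integer(1), "experiment_id"),
      source_region_id = vapply(experiments, `[[`, integer(1),
                                "source_region"))
  } else {
    data.frame(injection_id = integer(0), source_region_id = integer(0))
  }
  DBI::dbWriteTable(con, "injection2regionID", inj_df)

  if (is.null(pair_medians) || nrow(pair_medians) == 0L) {
    pair_medians <- data.frame(injection_id = integer(0),
                               median_value = numeric(0),
                               target_region = integer(0))
  }
  DBI::dbWriteTable(con, "injection2target", data.frame(
    injection_id = as.integer(pair_medians$injection_id),
    median_value = as.numeric(pair_medians$median_value),
    target_annotation_id = as.integer(pair_medians$target_region)))

  DBI::dbWriteTable(con, "meta", data.frame(
    key = c("schema_version", "dims", "resolution_um", "gene_ids"),
    value = c(as.character(.SCHEMA_VERSION),
              paste(annot$dims, collapse = ","),
              as.character(annot$resolution_um),
              paste(expr$gene_ids, collapse = ","))))
  invisible(path)
}

#' Load a processed atlas from an SQLite database
#'
#' Inverse of [store_database()]: reconstructs the annotation volume, the
#' full expression matrix (zero-filtered entries restored as 0), the
#' injection source map and the per-target medians.
#'
#' @param path SQLite file written by [store_database()].
#' @return list with elements `annotation`, `expression`, `injections`
#'   (data.frame `injection_id`, `source_region_id`) and `pair_medians`
#'   (data.frame `injection_id`, `median_value`, `target_region`).
#' @export
load_database <- function(path) {
  if (!file.exists(path)) stop("no such database: ", path, call. = FALSE)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))

  have <- DBI::dbListTables(con)
  missing <- setdiff(.REQUIRED_TABLES, have)
  if (length(missing)) {
    stop("schema error: missing table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- DBI::dbReadTable(con, "meta")
  meta_val <- function(key) meta$value[match(key, meta$key)]
  version <- as.integer(meta_val("schema_version"))
  if (is.na(version) || version != .SCHEMA_VERSION) {
    stop(sprintf("schema error: database schema version %s, expected %d",
                 meta_val("schema_version"), .SCHEMA_VERSION), call. = FALSE)
  }
  dims <- as.integer(strsplit(meta_val("dims"), ",")[[1]])
  resolution <- as.integer(meta_val("resolution_um"))
  gene_ids <- as.integer(strsplit(meta_val("gene_ids"), ",")[[1]])

  ann_df <- DBI::dbReadTable(con, "voxID2Annotation")
  region <- integer(prod(dims))
  region[ann_df$voxel_id + 1L] <- ann_df$structure_annotation
  annot <- annotation_volume(region, dims, resolution)

  ge <- DBI::dbReadTable(con, "voxID2GenExpr")
  values <- matrix(0, nrow = length(gene_ids), ncol = prod(dims))
  if (nrow(ge)) {
    values[cbind(match(ge$gene_id, gene_ids), ge$voxel_id + 1L)] <-
      ge$gene_expression_value
  }
  expr <- expression_matrix(values, gene_ids)

  inj <- DBI::dbReadTable(con, "injection2regionID")
  i2t <- DBI::dbReadTable(con, "injection2target")
  pair_medians <- data.frame(injection_id = i2t$injection_id,
                             median_value = i2t$median_value,
                             target_region = i2t$target_annotation_id)

  list(annotation = annot, expression = expr, injections = inj,
       pair_medians = pair_medians)
}
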
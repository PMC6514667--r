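# Volumetric grid containers and file formats: raw float32 expression
# volumes (with a JSON sidecar header), NRRD projection volumes, annotation
# vectors, the hierarchical structure graph, and the genes x voxels CSV.
#
# Linearization convention everywhere: first (x) index fastest — R's native
# array order — recorded in every header this package writes.

#' Annotation volume
#'
#' Maps each voxel of a 3D grid to a brain-region ID (0 = background /
#' unannotated), stored as a flat integer vector with the x index fastest.
#'
#' @param region_of_voxel integer vector, length `prod(dims)`.
#' @param dims integer triple.
#' @param resolution_um voxel edge length in micrometres.
#' @return an object of class `annotation_volume`.
#' @export
annotation_volume <- function(region_of_voxel, dims, resolution_um) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("`dims` must be a triple of positive integers", call. = FALSE)
  }
  if (length(region_of_voxel) != prod(dims)) {
    stop(sprintf("annotation length %d does not match prod(dims) = %d",
                 length(region_of_voxel), prod(dims)), call. = FALSE)
  }
  if (any(region_of_voxel < 0L)) {
    stop("region IDs must be >= 0 (0 = background)", call. = FALSE)
  }
  structure(list(dims = dims,
                 resolution_um = as.integer(resolution_um),
                 region_of_voxel = as.integer(region_of_voxel)),
            class = "annotation_volume")
}

#' Gene expression matrix (genes x voxels)
#'
#' @param values non-negative numeric matrix, rows = genes, columns = voxels
#'   aligned to the coarse annotation volume.
#' @param gene_ids gene identifiers, one per row.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = seq_len(nrow(values))) {
  stopifnot(is.matrix(values))
  if (length(gene_ids) != nrow(values)) {
    stop("`gene_ids` must have one entry per matrix row", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  rownames(values) <- as.character(gene_ids)
  structure(list(gene_ids = gene_ids,
                 voxel_count = ncol(values),
                 values = values),
            class = "expression_matrix")
}

#' One tracer-injection experiment
#'
#' @param experiment_id integer ID.
#' @param source_region region ID of the (primary) injection site.
#' @param projection flat non-negative numeric vector aligned to the fine
#'   annotation volume.
#' @param dims integer triple of the fine grid.
#' @param resolution_um fine-grid resolution.
#' @return an object of class `injection_experiment`.
#' @export
injection_experiment <- function(experiment_id, source_region, projection,
                                 dims, resolution_um = 100L) {
  dims <- as.integer(dims)
  if (length(projection) != prod(dims)) {
    stop("projection length does not match prod(dims)", call. = FALSE)
  }
  structure(list(experiment_id = as.integer(experiment_id),
                 source_region = as.integer(source_region),
                 projection = as.numeric(projection),
                 dims = dims,
                 resolution_um = as.integer(resolution_um)),
            class = "injection_experiment")
}

# ---------------------------------------------------------------------------
# raw float32 volumes (expression "energy" files) + JSON sidecar header

#' Write a raw float32 expression volume
#'
#' Values are stored as 32-bit little-endian IEEE floats, x index fastest; a
#' sidecar `<path>.json` records dims, resolution and the axis order.
#'
#' @param values numeric vector, length `prod(dims)`.
#' @param path output file path.
#' @param dims integer triple.
#' @param resolution_um grid resolution for the sidecar header.
#' @return `path`, invisibly.
#' @export
write_expression_volume <- function(values, path, dims,
                                    resolution_um = 200L) {
  dims <- as.integer(dims)
  if (length(values) != prod(dims)) {
    stop("`values` length does not match prod(dims)", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(dims = dims, resolution_um = as.integer(resolution_um),
         order = "x-fastest", dtype = "float32-le"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a raw float32 expression volume
#'
#' @param path file path.
#' @param dims integer triple; if `NULL`, read from the sidecar
#'   `<path>.json`.
#' @return numeric vector of length `prod(dims)`.
#' @export
read_expression_volume <- function(path, dims = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(dims)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("`dims` not given and sidecar header missing: ", sidecar,
           call. = FALSE)
    }
    dims <- as.integer(jsonlite::read_json(sidecar,
                                           simplifyVector = TRUE)$dims)
  }
  dims <- as.integer(dims)
  n_expected <- prod(dims)
  n_bytes <- file.size(path)
  if (n_bytes != 4L * n_expected) {
    stop(sprintf(
      "raw volume format error: expected %d float32 elements (%d bytes), file holds %s bytes (%.2f elements)",
      n_expected, 4L * n_expected, format(n_bytes), n_bytes / 4),
      call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, what = "numeric", n = n_expected, size = 4L,
          endian = "little")
}

# ---------------------------------------------------------------------------
# NRRD projection volumes (minimal NRRD0004, raw encoding, little endian)

#' Write a projection volume as NRRD
#'
#' Minimal NRRD0004: `type: float`, `encoding: raw`, `endian: little`,
#' 3-dimensional, x index fastest (NRRD's native axis order).
#'
#' @param values numeric vector of length `prod(dims)`.
#' @param path output file path.
#' @param dims integer triple.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(values, path, dims) {
  dims <- as.integer(dims)
  if (length(values) != prod(dims)) {
    stop("`values` length does not match prod(dims)", call. = FALSE)
  }
  header <- paste0(
    "NRRD0004\n",
    "# written by voxconn\n",
    "type: float\n",
    "dimension: 3\n",
    sprintf("sizes: %d %d %d\n", dims[1], dims[2], dims[3]),
    "encoding: raw\n",
    "endian: little\n",
    "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(values), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an NRRD projection volume
#'
#' Supports the subset this package writes (raw-encoded little-endian float,
#' 3-D); header dims are trusted and checked against the payload size.
#'
#' @param path NRRD file path.
#' @return list with `dims` (integer triple) and `values` (numeric vector).
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bytes <- readBin(path, what = "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(0x0a))
  sep <- nl[which(diff(nl) == 1L)[1]]
  if (is.na(sep)) stop("NRRD format error: no header terminator",
                       call. = FALSE)
  header <- strsplit(rawToChar(bytes[seq_len(sep)]), "\n", fixed = TRUE)[[1]]
  if (!startsWith(header[1], "NRRD")) {
    stop("NRRD format error: missing magic", call. = FALSE)
  }
  fields <- header[grepl(":", header, fixed = TRUE) & !startsWith(header, "#")]
  kv <- do.call(rbind, strsplit(fields, ":\\s*"))
  get_field <- function(name) kv[match(name, kv[, 1]), 2]
  if (!identical(get_field("encoding"), "raw") ||
      !identical(get_field("type"), "float")) {
    stop("NRRD format error: only raw-encoded float volumes are supported",
         call. = FALSE)
  }
  endian <- get_field("endian")
  if (!is.na(endian) && endian != "little") {
    stop("NRRD format error: only little-endian volumes are supported",
         call. = FALSE)
  }
  dims <- as.integer(strsplit(get_field("sizes"), "\\s+")[[1]])
  n_expected <- prod(dims)
  payload <- bytes[(sep + 2L):length(bytes)]
  if (length(payload) != 4L * n_expected) {
    stop(sprintf(
      "NRRD format error: header promises %d elements (%d bytes) but payload holds %d bytes",
      n_expected, 4L * n_expected, length(payload)), call. = FALSE)
  }
  list(dims = dims,
       values = readBin(payload, what = "numeric", n = n_expected,
                        size = 4L, endian = "little"))
}

#' Write/read an injection experiment as NRRD
#'
#' The experiment ID and source region travel in the file name
#' (`inj<EXPID>_src<REGION>.nrrd`) so a directory of projection volumes is
#' self-describing.
#'
#' @param exp an [injection_experiment()].
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
write_injection_nrrd <- function(exp, dir) {
  stopifnot(inherits(exp, "injection_experiment"))
  path <- file.path(dir, sprintf("inj%05d_src%04d.nrrd",
                                 exp$experiment_id, exp$source_region))
  write_nrrd(exp$projection, path, exp$dims)
  invisible(path)
}

#' @rdname write_injection_nrrd
#' @param path NRRD file written by [write_injection_nrrd()].
#' @param resolution_um resolution recorded on the restored object.
#' @export
read_injection_nrrd <- function(path, resolution_um = 100L) {
  m <- regmatches(basename(path),
                  regexec("^inj([0-9]+)_src([0-9]+)\\.nrrd$", basename(path)))[[1]]
  if (length(m) != 3L) {
    stop("not an injection NRRD filename: ", basename(path), call. = FALSE)
  }
  vol <- read_nrrd(path)
  injection_experiment(as.integer(m[2]), as.integer(m[3]), vol$values,
                       vol$dims, resolution_um)
}

# ---------------------------------------------------------------------------
# expression matrix CSV (genes as rows) and annotation CSV

#' Write/read the genes-by-voxels expression matrix as CSV
#'
#' One row per gene: `gene_id` followed by one column per voxel.
#'
#' @param expr an [expression_matrix()].
#' @param path CSV path.
#' @return `path` invisibly (write); an [expression_matrix()] (read).
#' @export
write_expression_csv <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = expr$gene_ids, expr$values,
                   check.names = FALSE)
  colnames(df) <- c("gene_id", sprintf("v%d", seq_len(ncol(expr$values)) - 1L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_csv
#' @export
read_expression_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(values) <- NULL
  expression_matrix(values, gene_ids = df$gene_id)
}

#' Write/read an annotation volume as CSV
#'
#' Two columns: 0-based `voxel_id` and `region_id`; dims and resolution go
#' in a sidecar `<path>.json`.
#'
#' @param annot an [annotation_volume()].
#' @param path CSV path.
#' @return `path` invisibly (write); an [annotation_volume()] (read).
#' @export
write_annotation_csv <- function(annot, path) {
  stopifnot(inherits(annot, "annotation_volume"))
  utils::write.csv(
    data.frame(voxel_id = seq_along(annot$region_of_voxel) - 1L,
               region_id = annot$region_of_voxel),
    path, row.names = FALSE)
  jsonlite::write_json(list(dims = annot$dims,
                            resolution_um = annot$resolution_um,
                            order = "x-fastest"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  df <- utils::read.csv(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  annotation_volume(df$region_id[order(df$voxel_id)],
                    as.integer(hdr$dims), as.integer(hdr$resolution_um))
}

# ---------------------------------------------------------------------------
# structure graph

#' Hierarchical structure graph
#'
#' The tree of brain structures: each node has an ID, an acronym and a
#' parent ID (`NA` for the single root). Validated on construction: unique
#' IDs, exactly one root, parents present, no cycles.
#'
#' @param nodes data.frame with columns `id`, `acronym`, `parent`.
#' @return an object of class `structure_graph`.
#' @export
structure_graph <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "acronym", "parent") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id)) {
    stop("structural error: duplicate node IDs", call. = FALSE)
  }
  roots <- which(is.na(nodes$parent))
  if (length(roots) != 1L) {
    stop("structural error: structure graph must have exactly one root",
         call. = FALSE)
  }
  known <- nodes$parent %in% nodes$id | is.na(nodes$parent)
  if (!all(known)) {
    stop("structural error: missing parent node(s): ",
         paste(nodes$parent[!known], collapse = ", "), call. = FALSE)
  }
  # cycle check: every node must reach the root in <= n steps
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  for (id in nodes$id) {
    cur <- id
    for (step in seq_len(nrow(nodes) + 1L)) {
      p <- parent_of[[as.character(cur)]]
      if (is.na(p)) break
      cur <- p
      if (step > nrow(nodes)) stop("structural error: cycle in structure graph",
                                   call. = FALSE)
    }
    if (!is.na(parent_of[[as.character(cur)]])) {
      stop("structural error: cycle in structure graph", call. = FALSE)
    }
  }
  structure(list(nodes = nodes), class = "structure_graph")
}

#' Write/read a structure graph as JSON
#'
#' @param graph a [structure_graph()].
#' @param path JSON path.
#' @return `path` invisibly (write); a [structure_graph()] (read).
#' @export
write_structure_graph <- function(graph, path) {
  stopifnot(inherits(graph, "structure_graph"))
  jsonlite::write_json(graph$nodes, path, na = "null")
  invisible(path)
}

#' @rdname write_structure_graph
#' @export
read_structure_graph <- function(path) {
  nodes <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(nodes$parent)) nodes$parent <- NA_integer_
  structure_graph(as.data.frame(nodes))
}

#' Roll annotation labels up to a target set of regions
#'
#' Replaces each voxel's region ID with its nearest ancestor (the region
#' itself counts) that belongs to `target_regions`; voxels whose ancestor
#' chain never meets the target set map to background `0`. This is how
#' annotations at different granularities are traced back to a common level
#' of the structure tree.
#'
#' @param annot an [annotation_volume()].
#' @param graph a [structure_graph()] containing every nonzero region ID in
#'   `annot` and every target region.
#' @param target_regions integer vector of region IDs to harmonize to.
#' @return an [annotation_volume()] with identical dims and resolution.
#' @export
harmonize_annotation <- function(annot, graph, target_regions) {
  stopifnot(inherits(annot, "annotation_volume"),
            inherits(graph, "structure_graph"))
  target_regions <- as.integer(target_regions)
  missing <- setdiff(target_regions, graph$nodes$id)
  if (length(missing)) {
    stop("structural error: target region(s) not in graph: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  parent_of <- stats::setNames(graph$nodes$parent, graph$nodes$id)
  targets <- as.character(target_regions)

  roll_up <- function(id) {
    cur <- id
    for (step in seq_len(nrow(graph$nodes) + 1L)) {
      if (as.character(cur) %in% targets) return(as.integer(cur))
      p <- parent_of[[as.character(cur)]]
      if (is.null(p) || is.na(p)) return(0L)
      cur <- p
    }
    stop("structural error: cycle in structure graph", call. = FALSE)
  }

  ids <- unique(annot$region_of_voxel)
  ids <- ids[ids != 0L]
  unknown <- setdiff(ids, graph$nodes$id)
  if (length(unknown)) {
    stop("structural error: annotation region(s) not in graph: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mapping <- vapply(ids, roll_up, integer(1))
  lut <- stats::setNames(c(0L, mapping), c(0L, ids))
  annotation_volume(unname(lut[as.character(annot$region_of_voxel)]),
                    annot$dims, annot$resolution_um)
}
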
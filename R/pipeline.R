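# Workflow orchestration: generate (or ingest) -> label -> build -> train ->
# evaluate, each stage writing its artifacts plus a JSON manifest (config
# hash, seeds, input hashes, row counts) under the output directory, so a
# finished run is auditable and reproducible from config + seed alone.

#' Pipeline configuration
#'
#' @param out_dir output directory; stage artifacts land in subdirectories.
#' @param synth a [synthetic_config()] (used by the `generate` stage).
#' @param scheme a [label_scheme()].
#' @param build a [build_config()].
#' @param mlp_args named list of overrides passed to [mlp_config()] at the
#'   train stage (`input_dim` and `mode` are filled in automatically).
#' @param input_dir directory of pre-existing atlas files for the `ingest`
#'   stage (alternative to `generate`).
#' @param by_pair use a pair-disjoint split (see [split_dataset()]).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            synth = synthetic_config(),
                            scheme = label_scheme("binary"),
                            build = build_config(M = 10L),
                            mlp_args = list(),
                            input_dir = NULL,
                            by_pair = FALSE) {
  stopifnot(inherits(synth, "synthetic_config"),
            inherits(scheme, "label_scheme"),
            inherits(build, "build_config"))
  structure(list(out_dir = out_dir, synth = synth, scheme = scheme,
                 build = build, mlp_args = mlp_args,
                 input_dir = input_dir, by_pair = by_pair),
            class = "pipeline_config")
}

# canonical hash of any jsonlite-serializable object
.config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(dir, stage, config, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage,
           config_hash = .config_hash(unclass_all(config)),
           seed = config$synth$seed),
      extra),
    file.path(dir, sprintf("manifest_%s.json", stage)),
    auto_unbox = TRUE, digits = NA, force = TRUE)
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else x
}

.require_upstream <- function(path, needed_stage) {
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact '%s': run stage '%s' first",
                 path, needed_stage), call. = FALSE)
  }
  invisible(path)
}

#' Run one pipeline stage
#'
#' Stages, in order: `generate` (write a synthetic atlas to disk; or
#' `ingest` to validate an existing atlas directory), `label` (median
#' aggregation + pair table + SQLite store), `build` (Source-Target
#' dataset), `train`, `evaluate`. Each stage reads only the files the
#' previous stages wrote, so stages are resumable; rerunning a stage with
#' unchanged inputs rewrites identical artifacts.
#'
#' @param stage one of `"generate"`, `"ingest"`, `"label"`, `"build"`,
#'   `"train"`, `"evaluate"`.
#' @param config a [pipeline_config()].
#' @return the stage's principal artifact, invisibly (see details per
#'   stage in the source).
#' @export
run_stage <- function(stage = c("generate", "ingest", "label", "build",
                                "train", "evaluate"),
                      config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  atlas_dir <- file.path(out, "atlas")
  switch(stage,
         generate = .stage_generate(config, atlas_dir),
         ingest = .stage_ingest(config, atlas_dir),
         label = .stage_label(config, atlas_dir),
         build = .stage_build(config, atlas_dir),
         train = .stage_train(config),
         evaluate = .stage_evaluate(config))
}

.stage_generate <- function(config, atlas_dir) {
  dir.create(file.path(atlas_dir, "expression"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(atlas_dir, "projections"), showWarnings = FALSE)
  atlas <- generate_atlas(config$synth)

  write_annotation_csv(atlas$annotation$coarse,
                       file.path(atlas_dir, "annotation_coarse.csv"))
  write_annotation_csv(atlas$annotation$fine,
                       file.path(atlas_dir, "annotation_fine.csv"))
  write_structure_graph(atlas$graph,
                        file.path(atlas_dir, "structure_graph.json"))
  for (i in seq_along(atlas$expression$gene_ids)) {
    write_expression_volume(
      atlas$expression$values[i, ],
      file.path(atlas_dir, "expression",
                sprintf("gene_%05d.raw", atlas$expression$gene_ids[i])),
      dims = atlas$annotation$coarse$dims, resolution_um = 200L)
  }
  for (exp in atlas$experiments) {
    write_injection_nrrd(exp, file.path(atlas_dir, "projections"))
  }
  jsonlite::write_json(unclass_all(config$synth),
                       file.path(atlas_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(atlas_dir, "generate", config, list(
    n_regions = config$synth$n_regions,
    n_genes = config$synth$n_genes,
    n_experiments = length(atlas$experiments)))
  message(sprintf("generate: %d regions, %d genes, %d experiments -> %s",
                  config$synth$n_regions, config$synth$n_genes,
                  length(atlas$experiments), atlas_dir))
  invisible(atlas_dir)
}

.stage_ingest <- function(config, atlas_dir) {
  if (is.null(config$input_dir)) {
    stop("ingest requires `input_dir` in the pipeline config", call. = FALSE)
  }
  needed <- c("annotation_coarse.csv", "annotation_fine.csv",
              "structure_graph.json", "expression", "projections")
  missing <- needed[!file.exists(file.path(config$input_dir, needed))]
  if (length(missing)) {
    stop("input directory lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dirname(atlas_dir), recursive = TRUE, showWarnings = FALSE)
  if (normalizePath(config$input_dir) != suppressWarnings(normalizePath(atlas_dir))) {
    unlink(atlas_dir, recursive = TRUE)
    dir.create(atlas_dir, recursive = TRUE)
    file.copy(list.files(config$input_dir, full.names = TRUE), atlas_dir,
              recursive = TRUE)
  }
  .write_manifest(atlas_dir, "ingest", config,
                  list(source = config$input_dir))
  invisible(atlas_dir)
}

# read an atlas directory back into memory
read_atlas_dir <- function(atlas_dir) {
  annot_c <- read_annotation_csv(file.path(atlas_dir,
                                           "annotation_coarse.csv"))
  annot_f <- read_annotation_csv(file.path(atlas_dir,
                                           "annotation_fine.csv"))
  graph <- read_structure_graph(file.path(atlas_dir,
                                          "structure_graph.json"))
  raw_files <- sort(list.files(file.path(atlas_dir, "expression"),
                               pattern = "\\.raw$", full.names = TRUE))
  gene_ids <- as.integer(sub("^gene_0*([0-9]+)\\.raw$", "\\1",
                             basename(raw_files)))
  values <- do.call(rbind, lapply(raw_files, read_expression_volume))
  expr <- expression_matrix(values, gene_ids)
  nrrd_files <- sort(list.files(file.path(atlas_dir, "projections"),
                                pattern = "\\.nrrd$", full.names = TRUE))
  experiments <- lapply(nrrd_files, read_injection_nrrd)
  list(annotation = list(coarse = annot_c, fine = annot_f), graph = graph,
       expression = expr, experiments = experiments)
}

.stage_label <- function(config, atlas_dir) {
  .require_upstream(file.path(atlas_dir, "annotation_fine.csv"),
                    "generate")
  atlas <- read_atlas_dir(atlas_dir)
  medians <- injection_target_medians(atlas$experiments,
                                      atlas$annotation$fine)
  pairs <- pair_connectivity_table(atlas$experiments,
                                   atlas$annotation$fine,
                                   scheme = config$scheme)
  write_pair_table(pairs, file.path(config$out_dir, "pairs.csv"))
  store_database(file.path(config$out_dir, "atlas.sqlite"),
                 atlas$annotation$coarse, atlas$expression,
                 atlas$experiments,
                 medians[, c("injection_id", "median_value",
                             "target_region")])
  .write_manifest(config$out_dir, "label", config, list(
    n_pairs = nrow(pairs),
    n_excluded = sum(is.na(pairs$label)),
    class_sizes = as.list(table(pairs$label, useNA = "no"))))
  message(sprintf("label: %d pairs (%d excluded by threshold gap); classes: %s",
                  nrow(pairs), sum(is.na(pairs$label)),
                  paste(names(table(pairs$label)), table(pairs$label),
                        sep = "=", collapse = " ")))
  invisible(pairs)
}

.stage_build <- function(config, atlas_dir) {
  pairs_path <- .require_upstream(file.path(config$out_dir, "pairs.csv"),
                                  "label")
  atlas <- read_atlas_dir(atlas_dir)
  pairs <- utils::read.csv(pairs_path)
  built <- build_st_dataset(pairs, atlas$annotation$coarse,
                            atlas$expression, config$build,
                            by_pair = config$by_pair)
  write_dataset_csv(built, config$build,
                    file.path(config$out_dir, "dataset"))
  .write_manifest(config$out_dir, "build", config,
                  c(built$log[c("n_pairs", "n_vectors_built",
                                "n_vectors_after_caps")],
                    list(split_sizes = as.list(built$log$split_sizes))))
  message(sprintf("build: %d vectors from %d pairs -> train/val/test %s",
                  built$log$n_vectors_after_caps, built$log$n_pairs,
                  paste(built$log$split_sizes, collapse = "/")))
  invisible(built)
}

# read a dataset directory written by write_dataset_csv back into a split
read_dataset_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  parts <- lapply(c(train = "train", validation = "validation",
                    test = "test"), function(p) {
    df <- utils::read.csv(file.path(dir, paste0(p, ".csv")))
    feat_cols <- grepl("^f[0-9]+$", names(df))
    st_dataset(as.matrix(df[, feat_cols, drop = FALSE]) |>
                 (\(m) {dimnames(m) <- NULL; m})(),
               df[, !feat_cols, drop = FALSE])
  })
  split <- structure(c(parts,
                       list(fractions = unlist(manifest$fractions),
                            seed = manifest$seed, by_pair = FALSE)),
                     class = "dataset_split")
  list(split = split, manifest = manifest)
}

.stage_train <- function(config) {
  ds_dir <- file.path(config$out_dir, "dataset")
  .require_upstream(file.path(ds_dir, "train.csv"), "build")
  ds <- read_dataset_dir(ds_dir)
  args <- config$mlp_args
  args$input_dim <- ncol(ds$split$train$features)
  if (is.null(args$mode)) {
    args$mode <- if (config$scheme$mode == "multiclass") "multiclass"
                 else "binary"
  }
  cfg <- do.call(mlp_config, args)
  fit <- train_mlp(build_mlp(cfg), ds$split)
  save_mlp(fit$model, file.path(config$out_dir, "model.json"))
  utils::write.csv(fit$history,
                   file.path(config$out_dir, "history.csv"),
                   row.names = FALSE)
  .write_manifest(config$out_dir, "train", config, list(
    epochs = cfg$epochs,
    final_train_accuracy = utils::tail(fit$history$accuracy, 1),
    final_val_accuracy = utils::tail(fit$history$val_accuracy, 1)))
  message(sprintf("train: %d epochs; final train acc %.3f, val acc %.3f",
                  cfg$epochs,
                  utils::tail(fit$history$accuracy, 1),
                  utils::tail(fit$history$val_accuracy, 1)))
  invisible(fit)
}

.stage_evaluate <- function(config) {
  model_path <- .require_upstream(file.path(config$out_dir, "model.json"),
                                  "train")
  model <- load_mlp(model_path)
  ds <- read_dataset_dir(file.path(config$out_dir, "dataset"))
  history <- utils::read.csv(file.path(config$out_dir, "history.csv"))
  report <- evaluate_mlp(model, ds$split$test, history = history)
  write_eval_report(report, file.path(config$out_dir, "eval_report.json"))
  .write_manifest(config$out_dir, "evaluate", config, list(
    accuracy = report$accuracy,
    auc = if (is.null(report$auc)) NA else report$auc,
    n_test = report$n_test))
  message(sprintf("evaluate: accuracy %.3f%s on %d test vectors",
                  report$accuracy,
                  if (is.null(report$auc)) ""
                  else sprintf(", AUC %.3f", report$auc),
                  report$n_test))
  invisible(report)
}

#' Run the full pipeline
#'
#' `generate -> label -> build -> train -> evaluate` in order.
#'
#' @param config a [pipeline_config()].
#' @return the final [evaluate_mlp()] report, invisibly.
#' @export
run_pipeline <- function(config) {
  for (stage in c("generate", "label", "build", "train")) {
    run_stage(stage, config)
  }
  run_stage("evaluate", config)
}
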
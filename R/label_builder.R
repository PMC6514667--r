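# Connectivity aggregation and class labeling: per-experiment medians over a
# target region's voxels, max across experiments for the same ordered pair,
# then empirical thresholds that turn the aggregated value into a class.

#' Labeling scheme for aggregated connectivity values
#'
#' Multiclass: 0 = unconnected (`c == 0`), 1 = weakly connected
#' (`t_low <= c < t_high`), 2 = strongly connected (`c >= t_high`).
#' Binary: 0 = unconnected (`c == 0`), 1 = connected (`c > t_low`).
#' Values strictly between 0 and `t_low` (and, in the binary task, exactly
#' `t_low`) belong to no class and are excluded from datasets.
#'
#' @param mode `"multiclass"` or `"binary"`.
#' @param t_low lower threshold (default 0.006).
#' @param t_high upper threshold (default 0.1, multiclass only).
#' @return an object of class `label_scheme`.
#' @export
label_scheme <- function(mode = c("multiclass", "binary"),
                         t_low = 0.006, t_high = 0.1) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(t_low, "t_low")
  stopifnot_scalar_number(t_high, "t_high")
  if (!(0 < t_low && t_low < t_high)) {
    stop("need 0 < t_low < t_high", call. = FALSE)
  }
  structure(list(mode = mode, t_low = t_low, t_high = t_high),
            class = "label_scheme")
}

#' Number of classes of a labeling scheme
#' @param scheme a [label_scheme()].
#' @return 3 for multiclass, 2 for binary.
#' @export
n_classes <- function(scheme) {
  if (scheme$mode == "multiclass") 3L else 2L
}

#' Median projection value of one experiment over one target region
#'
#' The median is taken over the projection values of exactly the fine
#' voxels annotated as `target_region` — all of them, including zeros,
#' since the projection volume defines a value at every voxel. The usual
#' even-count convention applies (mean of the two middle values).
#'
#' @param exp an [injection_experiment()].
#' @param target_region region ID.
#' @param annot_fine the fine [annotation_volume()] aligned with
#'   `exp$projection`.
#' @return the median, a single non-negative number.
#' @export
experiment_target_median <- function(exp, target_region, annot_fine) {
  stopifnot(inherits(exp, "injection_experiment"),
            inherits(annot_fine, "annotation_volume"))
  if (length(exp$projection) != length(annot_fine$region_of_voxel)) {
    stop("projection and annotation volumes have different lengths",
         call. = FALSE)
  }
  idx <- annot_fine$region_of_voxel == target_region
  if (!any(idx)) {
    stop(sprintf("empty region: target region %d has no voxels in the annotation",
                 target_region), call. = FALSE)
  }
  stats::median(exp$projection[idx])
}

#' Aggregate per-experiment medians into one pair connectivity value
#'
#' The final connectivity of an ordered Source-Target pair is the maximum of
#' the median values contributed by all experiments injected into the
#' source. The max discounts peripheral injections that under-report the
#' projection and keeps the best-placed experiment as representative.
#'
#' @param medians non-empty numeric vector of per-experiment medians, all
#'   `>= 0`.
#' @return `max(medians)`.
#' @export
aggregate_pair <- function(medians) {
  if (length(medians) == 0L) {
    stop("no experiments for this pair: cannot aggregate an empty median list (the pair is absent, not zero)",
         call. = FALSE)
  }
  if (any(is.na(medians)) || any(medians < 0)) {
    stop("medians must be non-negative and non-missing", call. = FALSE)
  }
  max(medians)
}

#' Assign a class label to an aggregated connectivity value
#'
#' Vectorized. Multiclass: `c == 0 -> 0`; `t_low <= c < t_high -> 1`;
#' `c >= t_high -> 2`; `0 < c < t_low -> NA` (excluded). Binary:
#' `c == 0 -> 0`; `c > t_low -> 1`; `0 < c <= t_low -> NA` (excluded).
#' The boundary `c == t_high` goes to class 2 (strong connectivity treated
#' as `>= t_high`).
#'
#' @param c numeric vector of aggregated connectivity values, all `>= 0`.
#' @param scheme a [label_scheme()].
#' @return integer vector of class labels; `NA` marks excluded values.
#' @export
assign_label <- function(c, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  if (any(is.na(c)) || any(c < 0)) {
    stop("domain error: connectivity values must be non-negative and non-missing",
         call. = FALSE)
  }
  if (scheme$mode == "multiclass") {
    ifelse(c == 0, 0L,
           ifelse(c >= scheme$t_high, 2L,
                  ifelse(c >= scheme$t_low, 1L, NA_integer_)))
  } else {
    ifelse(c == 0, 0L, ifelse(c > scheme$t_low, 1L, NA_integer_))
  }
}

#' Per-experiment, per-target medians for a set of experiments
#'
#' One row per (injection, target region): the median projection value over
#' that region's fine voxels. These rows are what the `injection2target`
#' database table stores.
#'
#' @param experiments list of [injection_experiment()].
#' @param annot_fine the fine [annotation_volume()].
#' @param regions region IDs to evaluate as targets; defaults to every
#'   nonzero region present in `annot_fine`.
#' @return data.frame with columns `injection_id`, `source_region`,
#'   `target_region`, `median_value`.
#' @export
injection_target_medians <- function(experiments, annot_fine,
                                     regions = NULL) {
  stopifnot(inherits(annot_fine, "annotation_volume"))
  if (is.null(regions)) {
    regions <- sort(unique(annot_fine$region_of_voxel))
    regions <- regions[regions != 0L]
  }
  vox_of <- lapply(regions, function(r) {
    which(annot_fine$region_of_voxel == r)
  })
  empty <- lengths(vox_of) == 0L
  if (any(empty)) {
    stop("empty region: no voxels annotated as region(s) ",
         paste(regions[empty], collapse = ", "), call. = FALSE)
  }
  rows <- lapply(experiments, function(exp) {
    med <- vapply(vox_of, function(v) stats::median(exp$projection[v]),
                  numeric(1))
    data.frame(injection_id = exp$experiment_id,
               source_region = exp$source_region,
               target_region = regions,
               median_value = med)
  })
  do.call(rbind, rows)
}

#' Aggregated connectivity table for all ordered region pairs
#'
#' Runs the full two-stage aggregation: per-experiment medians via
#' [injection_target_medians()], then the max across experiments sharing a
#' source, per ordered (source, target) pair. Self-pairs are dropped.
#'
#' @param experiments list of [injection_experiment()].
#' @param annot_fine the fine [annotation_volume()].
#' @param regions optional target region IDs (default: all annotated).
#' @param scheme optional [label_scheme()]; when given, a `label` column is
#'   added (`NA` = excluded by the threshold gap).
#' @return data.frame with columns `source_region`, `target_region`,
#'   `value`, `n_experiments` (and `label` if `scheme` is given).
#' @export
pair_connectivity_table <- function(experiments, annot_fine,
                                    regions = NULL, scheme = NULL) {
  med <- injection_target_medians(experiments, annot_fine, regions)
  med <- med[med$source_region != med$target_region, , drop = FALSE]
  key <- interaction(med$source_region, med$target_region, drop = TRUE)
  agg <- do.call(rbind, lapply(split(med, key), function(df) {
    data.frame(source_region = df$source_region[1],
               target_region = df$target_region[1],
               value = aggregate_pair(df$median_value),
               n_experiments = nrow(df))
  }))
  agg <- agg[order(agg$source_region, agg$target_region), , drop = FALSE]
  rownames(agg) <- NULL
  if (!is.null(scheme)) agg$label <- assign_label(agg$value, scheme)
  agg
}

#' Export a pair-connectivity table as CSV
#'
#' @param pairs a [pair_connectivity_table()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}
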
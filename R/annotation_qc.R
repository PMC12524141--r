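# Annotation mask quality checks.
#
# Geometry comparison uses header dimensions only (in-plane matrix and
# slice count); spatial re-alignment via affines is a separate curation
# step, not performed here. The counting unit for label summaries is one
# annotated label instance per mask file per distinct nonzero label code
# (connected-component counting is deliberately not required).

#' Check a mask's labels against the configured vocabulary
#'
#' Every nonzero label in the mask must appear in the vocabulary for its
#' (cancer type, modality); unknown codes are returned with voxel counts.
#'
#' @param annotation a `qc_annotation`.
#' @param vocab label vocabulary (list of `{code, name, class}` entries),
#'   e.g. from [lookup_vocabulary()].
#' @return data.frame of violations (`label`, `voxels`); zero rows when
#'   all labels are known. An all-zero mask has nothing to check.
#' @export
check_label_vocabulary <- function(annotation, vocab) {
  if (is.null(vocab)) stopf("no label vocabulary configured for this mask")
  allowed <- vapply(vocab, function(v) as.integer(v$code), 0L)
  lab <- annotation$labels
  bad <- lab[lab$label != 0 & !(lab$label %in% allowed), , drop = FALSE]
  rownames(bad) <- NULL
  names(bad) <- c("label", "voxels")
  bad
}

#' Geometric consistency between a mask and its imaging series
#'
#' Consistent iff the in-plane dimensions (rows x columns) are equal AND
#' the mask's slice count equals the series instance count. Otherwise the
#' status names which of the two comparisons failed.
#'
#' @param annotation a `qc_annotation`.
#' @param series one row of the index's `series` data.frame (needs
#'   `n_instances` and `path`), or a `qc_series`; in-plane dimensions are
#'   taken from the series' instances.
#' @param series_dims optional `c(rows, cols, n_instances)` overriding the
#'   series lookup.
#' @return object of class `qc_consistency`: `status` (one of
#'   `consistent`, `roi_mismatch`, `slice_mismatch`, `both_mismatch`),
#'   `mask_dims`, `series_dims`.
#' @export
check_geometry_consistency <- function(annotation, series = NULL,
                                       series_dims = NULL) {
  if (is.null(series_dims)) {
    if (inherits(series, "qc_series")) {
      inst <- series$instances
      series_dims <- c(inst$rows[1], inst$cols[1], series$n_instances)
    } else if (is.data.frame(series)) {
      rec <- read_series_header(series$path[1])
      inst <- rec$instances
      series_dims <- c(inst$rows[1], inst$cols[1], rec$n_instances)
    } else stopf("supply either series or series_dims")
  }
  md <- annotation$dims
  roi_ok <- isTRUE(md[1] == series_dims[1]) && isTRUE(md[2] == series_dims[2])
  slices_ok <- isTRUE(md[3] == series_dims[3])
  status <- if (roi_ok && slices_ok) "consistent"
  else if (!roi_ok && !slices_ok) "both_mismatch"
  else if (!roi_ok) "roi_mismatch" else "slice_mismatch"
  structure(list(status = status, mask_dims = md,
                 series_dims = as.integer(series_dims)),
            class = "qc_consistency")
}

#' @export
print.qc_consistency <- function(x, ...) {
  cat(sprintf("<qc_consistency> %s (mask %s vs series %s)\n", x$status,
              paste(x$mask_dims, collapse = "x"),
              paste(x$series_dims, collapse = "x")))
  invisible(x)
}

#' Is an annotation empty?
#'
#' `TRUE` iff every voxel is zero - meaning nothing in the image required
#' annotation (e.g. a control case or a cleared follow-up), which is
#' meaningful content, not an error.
#'
#' @param annotation a `qc_annotation`.
#' @return logical flag.
#' @export
is_empty_annotation <- function(annotation) {
  all(annotation$labels$label == 0)
}

#' Annotation-vs-series consistency metric over a repository
#'
#' Runs [check_geometry_consistency()] and [is_empty_annotation()] for every
#' linked mask in the index. Orphan masks (no matching series) are
#' integrity-relevant and reported separately, not silently dropped.
#'
#' @param index a `qc_repo_index`.
#' @return list with `metric` (a [qc_metric()], record = linked mask, pass
#'   = geometrically consistent), `empty` (data.frame mask/empty flag),
#'   `empty_pct`, `statuses` (per-mask status data.frame) and `orphans`.
#' @export
annotation_consistency <- function(index) {
  ann <- index$annotations
  orphans <- ann[ann$orphan, , drop = FALSE]
  linked <- ann[!ann$orphan, , drop = FALSE]
  rows <- list(); statuses <- list(); empties <- list()
  for (i in seq_len(nrow(linked))) {
    a <- read_annotation(linked$path[i])
    ser <- index$series[index$series$provider == linked$provider[i] &
                          index$series$patient_id == linked$patient_id[i] &
                          index$series$series_id == linked$series_id[i], ,
                        drop = FALSE]
    st <- check_geometry_consistency(a, series = ser)
    statuses[[length(statuses) + 1L]] <- data.frame(
      path = linked$path[i], status = st$status, stringsAsFactors = FALSE)
    empties[[length(empties) + 1L]] <- data.frame(
      path = linked$path[i], empty = is_empty_annotation(a),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      record = linked$path[i], pass = st$status == "consistent",
      reason = if (st$status == "consistent") "" else st$status,
      stringsAsFactors = FALSE)
  }
  empty_df <- rbind_all(empties, c("path", "empty"))
  list(metric = qc_metric("annotation_consistency",
                          rbind_all(rows, c("record", "pass", "reason"))),
       statuses = rbind_all(statuses, c("path", "status")),
       empty = empty_df,
       empty_pct = pct_of(sum(empty_df$empty), nrow(empty_df), digits = 1),
       orphans = orphans)
}

#' Annotation timepoint coverage
#'
#' For each (cancer type, modality), counts patients by the number k of
#' distinct timepoints at which they have at least one annotation for that
#' modality. Rows are mutually exclusive per (patient, modality), so row
#' sums equal the number of annotated patients.
#'
#' @param index a `qc_repo_index`.
#' @param cancer_by_patient optional named character vector mapping
#'   patient_id to cancer type (e.g. from the clinical table); unknown
#'   patients are grouped under `"unknown"`.
#' @return data.frame `cancer_type`, `modality`, `timepoints` (k),
#'   `patients`.
#' @export
timepoint_coverage <- function(index, cancer_by_patient = NULL) {
  ann <- index$annotations
  ann <- ann[!is.na(ann$timepoint) & !is.na(ann$modality), , drop = FALSE]
  if (nrow(ann) == 0) {
    return(data.frame(cancer_type = character(), modality = character(),
                      timepoints = integer(), patients = integer(),
                      stringsAsFactors = FALSE))
  }
  ann$cancer_type <- if (is.null(cancer_by_patient)) "unknown" else {
    ct <- unname(cancer_by_patient[ann$patient_id])
    ifelse(is.na(ct), "unknown", ct)
  }
  key <- paste(ann$cancer_type, ann$modality, ann$patient_id, sep = "\r")
  k_per <- tapply(ann$timepoint, key, function(t) length(unique(t)))
  parts <- do.call(rbind, strsplit(names(k_per), "\r", fixed = TRUE))
  df <- data.frame(cancer_type = parts[, 1], modality = parts[, 2],
                   timepoints = as.integer(k_per), stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(patients = rep(1L, nrow(df))),
                          by = df[c("cancer_type", "modality", "timepoints")],
                          FUN = sum)
  agg[order(agg$cancer_type, agg$modality, agg$timepoints), , drop = FALSE]
}

#' Malignant/benign share of annotation labels
#'
#' The counting unit is one label instance: a (mask file, distinct nonzero
#' label code) pair. The denominator n is all label instances, including
#' classes tagged neither malignant nor benign, matching how annotation
#' areas are tallied in repository summaries; percentages are half-up to 1
#' decimal.
#'
#' @param annotations list of `qc_annotation` objects (one cancer/modality
#'   set).
#' @param vocab label vocabulary with class tags (`malignant`, `benign`,
#'   `other`).
#' @return list `malignant_pct`, `benign_pct`, `n` (label instances),
#'   `counts` (per class). With n = 0 the percentages are `NA` and a
#'   warning is emitted.
#' @export
label_class_summary <- function(annotations, vocab) {
  if (is.null(vocab)) stopf("no label vocabulary configured")
  class_of <- setNames(vapply(vocab, function(v) v$class %||% "other", ""),
                       vapply(vocab, function(v) as.character(v$code), ""))
  n <- 0L; counts <- c(malignant = 0L, benign = 0L, other = 0L)
  for (a in annotations) {
    labs <- a$labels$label[a$labels$label != 0]
    for (l in labs) {
      n <- n + 1L
      cl <- class_of[as.character(l)]
      cl <- if (is.na(cl)) "other" else cl
      counts[cl] <- counts[cl] + 1L
    }
  }
  if (n == 0) warnf("no labeled regions; malignant/benign shares undefined")
  list(malignant_pct = pct_of(counts[["malignant"]], n, digits = 1),
       benign_pct = pct_of(counts[["benign"]], n, digits = 1),
       n = n, counts = as.list(counts))
}
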
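# Repository scanning and the shared data model.
#
# Layout convention (configurable through the rule-set):
#   <root>/<PROVIDER>/<PATIENT_ID>/<T{n}>/<MODALITY>/<SERIES_ID>/*.dcm
# with annotation masks as sibling files <SERIES_ID>_annotation.nii[.gz]
# inside the modality directory, and one clinical CSV per cancer type at the
# root (clinical_<cancer_type>.csv). Scanning is deterministic: directories
# are visited in locale-independent lexicographic order.

list_dirs <- function(path) {
  d <- list.dirs(path, recursive = FALSE, full.names = FALSE)
  sort_c(d[!startsWith(d, ".")])
}

#' Scan a repository tree into an index
#'
#' Walks the provider/patient/timepoint/modality/series layout, reads every
#' DICOM header, and links annotation masks to their series. Directories
#' that violate the naming convention are still indexed, carrying a
#' naming-violation flag that the integrity dimension consumes. Unparseable
#' DICOM files are skipped with a per-file warning and counted.
#'
#' @param root_path repository root directory.
#' @param ruleset a `qc_ruleset` (supplies the layout convention); `NULL`
#'   loads the shipped default.
#' @return object of class `qc_repo_index` with data.frames `patients`,
#'   `series`, `instances`, `annotations`, plus `skipped` files and
#'   accumulated `warnings`.
#' @export
scan_repository <- function(root_path, ruleset = NULL) {
  if (!dir.exists(root_path)) stopf("repository root not readable: %s", root_path)
  rs <- ruleset %||% load_ruleset()
  tp_pat <- rs$layout$timepoint_pattern
  mask_suffix <- rs$layout$mask_suffix
  codes <- unlist(rs$modality_codes)

  patients <- list(); series <- list(); instances <- list()
  annotations <- list(); skipped <- list(); warns <- character()

  for (prov in list_dirs(root_path)) {
    prov_path <- file.path(root_path, prov)
    for (pat in list_dirs(prov_path)) {
      pat_path <- file.path(prov_path, pat)
      patients[[length(patients) + 1L]] <-
        data.frame(provider = prov, patient_id = pat, stringsAsFactors = FALSE)
      for (tpd in list_dirs(pat_path)) {
        tp_path <- file.path(pat_path, tpd)
        tp_ok <- grepl(tp_pat, tpd)
        tp <- if (tp_ok) as.integer(sub(tp_pat, "\\1", tpd)) else {
          digs <- regmatches(tpd, regexpr("[0-9]+", tpd))
          if (length(digs) == 1) as.integer(digs) else NA_integer_
        }
        for (modd in list_dirs(tp_path)) {
          mod_path <- file.path(tp_path, modd)
          if (modd %in% codes) {
            mod <- modd; mod_ok <- TRUE
          } else {
            hit <- codes[toupper(modd) == codes |
                           startsWith(toupper(modd), paste0(codes, "_"))]
            mod <- if (length(hit) > 0) hit[1] else NA_character_
            mod_ok <- FALSE
          }
          # annotation masks: sibling files <series>_annotation.nii[.gz]
          mask_files <- sort_c(list.files(mod_path, pattern = "\\.nii(\\.gz)?$"))
          mask_for <- list()
          for (mf in mask_files) {
            base <- sub("\\.nii(\\.gz)?$", "", mf)
            if (endsWith(base, mask_suffix)) {
              sid <- substr(base, 1, nchar(base) - nchar(mask_suffix))
              mask_for[[sid]] <- file.path(mod_path, mf)
            }
          }
          series_dirs <- list_dirs(mod_path)
          for (sid in series_dirs) {
            sdir <- file.path(mod_path, sid)
            rec <- tryCatch(read_series_header(sdir),
                            error = function(e) NULL)
            if (is.null(rec)) {
              warns <- c(warns, sprintf("series with no readable instances: %s", sdir))
              skipped[[length(skipped) + 1L]] <-
                data.frame(file = sdir, reason = "no readable instances",
                           stringsAsFactors = FALSE)
              next
            }
            warns <- c(warns, rec$warnings)
            if (length(rec$skipped) > 0) {
              skipped[[length(skipped) + 1L]] <-
                data.frame(file = rec$skipped, reason = "unparseable DICOM file",
                           stringsAsFactors = FALSE)
            }
            series[[length(series) + 1L]] <- data.frame(
              provider = prov, patient_id = pat, timepoint = tp,
              modality = mod, modality_dir = modd, naming_ok = mod_ok && tp_ok,
              series_id = sid, path = sdir, n_instances = rec$n_instances,
              mask_path = mask_for[[sid]] %||% NA_character_,
              stringsAsFactors = FALSE)
            inst <- rec$instances
            inst$provider <- prov; inst$patient_id <- pat
            inst$timepoint <- tp; inst$modality <- mod; inst$series_id <- sid
            instances[[length(instances) + 1L]] <- inst
            mask_for[[sid]] <- NULL
          }
          # masks with no matching series directory are orphans
          for (sid in names(mask_for)) {
            annotations[[length(annotations) + 1L]] <- data.frame(
              path = mask_for[[sid]], provider = prov, patient_id = pat,
              timepoint = tp, modality = mod, series_id = sid, orphan = TRUE,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  series_df <- rbind_all(series, c("provider", "patient_id", "timepoint",
                                   "modality", "modality_dir", "naming_ok",
                                   "series_id", "path", "n_instances", "mask_path"))
  linked <- series_df[!is.na(series_df$mask_path),
                      c("mask_path", "provider", "patient_id", "timepoint",
                        "modality", "series_id")]
  if (nrow(linked) > 0) {
    names(linked)[1] <- "path"
    linked$orphan <- FALSE
    annotations[[length(annotations) + 1L]] <- linked
  }
  structure(list(
    root = normalizePath(root_path),
    patients = rbind_all(patients, c("provider", "patient_id")),
    series = series_df,
    instances = rbind_all(instances, NULL),
    annotations = rbind_all(annotations, c("path", "provider", "patient_id",
                                           "timepoint", "modality", "series_id",
                                           "orphan")),
    skipped = rbind_all(skipped, c("file", "reason")),
    warnings = warns), class = "qc_repo_index")
}

rbind_all <- function(lst, cols) {
  if (length(lst) == 0) {
    if (is.null(cols)) return(data.frame())
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  do.call(rbind, lst)
}

#' Read all DICOM headers of a series directory
#'
#' Extracts the audit-relevant header attributes of every part-10 file in
#' the directory. Absent tags are recorded as `NA` (never defaulted);
#' unparseable files are skipped and listed.
#'
#' @param series_dir directory holding `.dcm` files.
#' @return object of class `qc_series`: `path`, `n_instances` (number of
#'   part-10 files present), per-instance `instances` data.frame, `skipped`
#'   file paths and `warnings`.
#' @export
read_series_header <- function(series_dir) {
  files <- sort_c(list.files(series_dir, pattern = "\\.dcm$", ignore.case = TRUE))
  if (length(files) == 0) stopf("no DICOM instances in %s", series_dir)
  rows <- list(); skipped <- character(); warns <- character()
  for (f in files) {
    fp <- file.path(series_dir, f)
    d <- tryCatch(dicom_read(fp), error = function(e) e)
    if (inherits(d, "error")) {
      warns <- c(warns, sprintf("skipping unparseable DICOM file %s: %s",
                                fp, conditionMessage(d)))
      skipped <- c(skipped, fp)
      rows[[length(rows) + 1L]] <- instance_row(fp, NULL, readable = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- instance_row(fp, d$attributes, readable = TRUE)
  }
  if (all(!vapply(rows, function(r) r$readable, TRUE)))
    stopf("no readable DICOM instances in %s", series_dir)
  structure(list(path = series_dir, n_instances = length(files),
                 instances = do.call(rbind, rows),
                 skipped = skipped, warnings = warns),
            class = "qc_series")
}

instance_row <- function(path, a, readable) {
  g <- function(nm, kind = "chr") {
    v <- a[[nm]]
    if (is.null(v) || length(v) == 0) {
      return(switch(kind, chr = NA_character_, num = NA_real_))
    }
    if (kind == "num") as.numeric(v[1]) else as.character(v[1])
  }
  ps <- a$PixelSpacing
  data.frame(
    file = path, readable = readable,
    uid = g("MediaStorageSOPInstanceUID"),
    sop_class = g("SOPClassUID"),
    header_modality = g("Modality"),
    rows = g("Rows", "num"), cols = g("Columns", "num"),
    pixel_spacing_row = if (length(ps) >= 1) ps[1] else NA_real_,
    pixel_spacing_col = if (length(ps) >= 2) ps[2] else NA_real_,
    slice_thickness = g("SliceThickness", "num"),
    manufacturer = g("Manufacturer"),
    field_strength = g("MagneticFieldStrength", "num"),
    convolution_kernel = g("ConvolutionKernel"),
    scanning_sequence = g("ScanningSequence"),
    patient_sex = g("PatientSex"),
    patient_age = g("PatientAge"),
    patient_name = g("PatientName"),
    patient_birth_date = g("PatientBirthDate"),
    header_patient_id = g("PatientID"),
    study_date = g("StudyDate"),
    burned_in = g("BurnedInAnnotation"),
    stringsAsFactors = FALSE)
}

#' Read an annotation mask
#'
#' Loads a NIfTI-1 volume of integer label codes. All-zero volumes load
#' without error (they are meaningful: nothing required annotation).
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return object of class `qc_annotation`: `path`, `dims`
#'   (rows, columns, slices), `labels` (data.frame of label code and voxel
#'   count, including 0), and total voxel count `n_voxels`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  arr <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("not a readable NIfTI file: %s (%s)",
                                            path, conditionMessage(e)))
  annotation_from_array(as.array(arr), path = path)
}

#' Build an annotation volume from an in-memory array
#'
#' @param arr 2-D or 3-D integer array of label codes.
#' @param path optional provenance path.
#' @return a `qc_annotation` (see [read_annotation()]).
#' @export
annotation_from_array <- function(arr, path = NA_character_) {
  d <- dim(arr)
  if (is.null(d)) stopf("annotation must be a 2-D or 3-D array")
  if (length(d) == 2) d <- c(d, 1L)
  if (length(d) > 3) d <- d[1:3]
  tab <- table(as.vector(arr))
  labels <- data.frame(label = as.integer(names(tab)),
                       voxels = as.integer(tab), stringsAsFactors = FALSE)
  labels <- labels[order(labels$label), , drop = FALSE]
  structure(list(path = path, dims = as.integer(d), labels = labels,
                 n_voxels = prod(d)), class = "qc_annotation")
}

#' @export
print.qc_annotation <- function(x, ...) {
  lab <- paste(x$labels$label, collapse = ",")
  cat(sprintf("<qc_annotation> %dx%dx%d labels {%s} (%s)\n",
              x$dims[1], x$dims[2], x$dims[3], lab,
              if (is.na(x$path)) "in-memory" else x$path))
  invisible(x)
}

#' Load a clinical metadata table
#'
#' Reads one clinical template CSV (one row per patient). Empty strings and
#' the configured missing-value sentinels (`NA`, `N/A`, `null`,
#' case-insensitive) all normalize to `NA`, so completeness does not depend
#' on site-specific blanks. Schema fields absent from the file are added as
#' all-missing columns; unknown columns are retained and flagged.
#'
#' @param path CSV file with a header row; must contain `patient_id`.
#' @param ruleset a `qc_ruleset` (supplies field rules and sentinels).
#' @return data.frame of class `qc_clinical` with attributes
#'   `unknown_columns` and `source`.
#' @export
load_clinical_table <- function(path, ruleset = NULL) {
  rs <- ruleset %||% load_ruleset()
  tbl <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!"patient_id" %in% names(tbl))
    stopf("clinical table %s lacks a patient_id column", path)
  for (j in seq_along(tbl)) {
    tbl[[j]][is_missing_value(tbl[[j]], unlist(rs$missing_sentinels))] <- NA
  }
  dup <- unique(tbl$patient_id[duplicated(tbl$patient_id)])
  if (length(dup) > 0)
    stopf("duplicated patient_id in %s: %s", path, paste(dup, collapse = ", "))
  if (any(is.na(tbl$patient_id)))
    stopf("empty patient_id value(s) in %s", path)
  decl_pat <- rs$modality_declarations$column_pattern
  schema <- c("patient_id", "provider", names(rs$field_rules))
  unknown <- setdiff(names(tbl), c(schema, grep(decl_pat, names(tbl), value = TRUE)))
  for (f in setdiff(schema, names(tbl))) tbl[[f]] <- NA_character_
  structure(tbl, class = c("qc_clinical", "data.frame"),
            unknown_columns = unknown, source = path)
}

#' Discover clinical tables at a repository root
#'
#' Finds `clinical_<cancer_type>.csv` files at the root and loads them into
#' one combined table.
#'
#' @inheritParams scan_repository
#' @return a `qc_clinical` table (possibly 0 rows), the row-wise union of
#'   all per-cancer-type files.
#' @export
load_clinical_tables <- function(root_path, ruleset = NULL) {
  rs <- ruleset %||% load_ruleset()
  files <- sort_c(list.files(root_path, pattern = "^clinical_.*\\.csv$",
                             full.names = TRUE))
  tabs <- lapply(files, load_clinical_table, ruleset = rs)
  if (length(tabs) == 0) {
    out <- data.frame(patient_id = character(), stringsAsFactors = FALSE)
    return(structure(out, class = c("qc_clinical", "data.frame"),
                     unknown_columns = character(), source = character()))
  }
  cols <- unique(unlist(lapply(tabs, names)))
  tabs <- lapply(tabs, function(t) {
    for (f in setdiff(cols, names(t))) t[[f]] <- NA_character_
    t[, cols, drop = FALSE]
  })
  out <- do.call(rbind, tabs)
  structure(out, class = c("qc_clinical", "data.frame"),
            unknown_columns = unique(unlist(lapply(tabs, attr, "unknown_columns"))),
            source = files)
}

#' @export
print.qc_repo_index <- function(x, ...) {
  cat(sprintf("<qc_repo_index> %s\n", x$root))
  cat(sprintf("  %d providers, %d patients, %d series, %d instances, %d masks\n",
              length(unique(x$patients$provider)), nrow(x$patients),
              nrow(x$series), nrow(x$instances), nrow(x$annotations)))
  if (nrow(x$skipped) > 0)
    cat(sprintf("  %d skipped files\n", nrow(x$skipped)))
  nv <- sum(!x$series$naming_ok)
  if (nv > 0) cat(sprintf("  %d series with naming violations\n", nv))
  invisible(x)
}
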
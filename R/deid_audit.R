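# De-identification compliance audit.
#
# Three violation categories, each advisory (curation lists, never
# modification of inputs):
#   retained_attribute - a header tag the de-id profile requires absent
#                        (patient sex/age/name/birth date) is present;
#   date_hash_mismatch - dates must be offset-hashed with the patient id:
#                        the in-header patient id must equal the
#                        folder-derived id, and all files of one patient at
#                        one timepoint must share one hashed date (one
#                        acquisition date per visit survives a common
#                        offset);
#   burnt_in_report    - pixel data depicts a textual report rather than an
#                        organ (header screen + color-spectrum classifier).

#' Deterministic date offset for a patient id
#'
#' The audit convention: every date tag of a patient is expected to be the
#' original date shifted by a per-patient offset in days, derived from the
#' patient id by a deterministic polynomial hash modulo `modulus` (default
#' 365). The audit never needs the true original date - it checks id
#' agreement and within-patient offset consistency.
#'
#' @param patient_id character id(s).
#' @param modulus offset modulus in days.
#' @return integer offset(s) in `[0, modulus)`.
#' @export
date_offset_days <- function(patient_id, modulus = 365) {
  vapply(patient_id, function(pid) {
    codes <- utf8ToInt(pid)
    h <- 0
    for (c in codes) h <- (h * 131 + c) %% 1e9
    as.integer(h %% modulus)
  }, 0L, USE.NAMES = FALSE)
}

# shift a DICOM DA string (YYYYMMDD) by n days
shift_dicom_date <- function(date_str, days) {
  d <- as.Date(date_str, format = "%Y%m%d") + days
  format(d, "%Y%m%d")
}

#' Audit retained (must-be-absent) header attributes
#'
#' One `retained_attribute` violation per present forbidden tag per
#' instance.
#'
#' @param series a `qc_series` (from [read_series_header()]) or an
#'   instance data.frame slice of an index.
#' @param profile de-id profile (the rule-set's `deid` block).
#' @return data.frame of violations: `file`, `category`, `detail`.
#' @export
audit_removed_attributes <- function(series, profile) {
  inst <- if (inherits(series, "qc_series")) series$instances else series
  forbidden <- unlist(profile$forbidden_attributes)
  col_of <- c(PatientSex = "patient_sex", PatientAge = "patient_age",
              PatientName = "patient_name", PatientBirthDate = "patient_birth_date")
  rows <- list()
  for (tag in forbidden) {
    col <- unname(col_of[tag])
    if (is.na(col) || !(col %in% names(inst))) next
    hit <- which(!is.na(inst[[col]]))
    for (i in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        file = inst$file[i], category = "retained_attribute",
        detail = tag, stringsAsFactors = FALSE)
    }
  }
  rbind_all(rows, c("file", "category", "detail"))
}

#' Audit hashed-date conventions for one patient
#'
#' Flags `date_hash_mismatch` when (a) a file's in-header patient id
#' differs from the folder-derived id (hashing was performed with the wrong
#' value, or the file sits in the wrong folder), or (b) date values are
#' mutually inconsistent within a (patient, timepoint): all files of one
#' visit must share one hashed date, so a file deviating from the modal
#' date breaks the single-offset expectation. Undated files are skipped.
#'
#' @param instances instance data.frame of one patient (index slice).
#' @param patient_id the folder-derived patient id.
#' @param profile de-id profile.
#' @return data.frame of violations: `file`, `category`, `detail`.
#' @export
audit_date_hashing <- function(instances, patient_id, profile) {
  inst <- instances
  rows <- list()
  bad_id <- which(!is.na(inst$header_patient_id) &
                    inst$header_patient_id != patient_id)
  for (i in bad_id) {
    rows[[length(rows) + 1L]] <- data.frame(
      file = inst$file[i], category = "date_hash_mismatch",
      detail = sprintf("header id %s != folder id %s",
                       inst$header_patient_id[i], patient_id),
      stringsAsFactors = FALSE)
  }
  dated <- inst[!is.na(inst$study_date), , drop = FALSE]
  if (nrow(dated) > 0) {
    for (tp in unique(dated$timepoint)) {
      sub <- dated[if (is.na(tp)) is.na(dated$timepoint) else
        !is.na(dated$timepoint) & dated$timepoint == tp, , drop = FALSE]
      dates <- sub$study_date
      if (length(unique(dates)) <= 1) next
      tab <- sort(table(dates), decreasing = TRUE)
      ref <- names(tab)[1]  # modal date; earliest on ties (table is sorted)
      off <- which(dates != ref)
      for (i in off) {
        rows[[length(rows) + 1L]] <- data.frame(
          file = sub$file[i], category = "date_hash_mismatch",
          detail = sprintf("date %s deviates from visit date %s",
                           dates[i], ref),
          stringsAsFactors = FALSE)
      }
    }
  }
  rbind_all(rows, c("file", "category", "detail"))
}

#' Screen instances for possible burnt-in content
#'
#' Recall-oriented: a candidate is any instance whose header suggests
#' secondary-capture or derived content (burned-in-annotation tag set to
#' YES, secondary-capture SOP class, modality OT) or whose pixel statistics
#' pass the report screen. Unreadable pixel data makes an instance a
#' candidate by caution. Over-flagging is acceptable; candidates go through
#' [classify_report_image()] before any violation is recorded.
#'
#' @param series a `qc_series` or instance data.frame.
#' @param classifier_params report-classifier thresholds (rule-set block).
#' @return data.frame of candidates: `file`, `reason`.
#' @export
screen_burnt_in_candidates <- function(series, classifier_params = NULL) {
  inst <- if (inherits(series, "qc_series")) series$instances else series
  cp <- classifier_params %||% list(background_fraction = 0.5,
                                    background_tolerance = 0.05,
                                    max_distinct_levels = 64)
  rows <- list()
  for (i in seq_len(nrow(inst))) {
    reason <- NULL
    if (!is.na(inst$burned_in[i]) && toupper(inst$burned_in[i]) == "YES") {
      reason <- "burned_in_annotation_tag"
    } else if (!is.na(inst$sop_class[i]) &&
               inst$sop_class[i] == SOP_CLASS_SECONDARY_CAPTURE) {
      reason <- "secondary_capture_sop_class"
    } else if (!is.na(inst$header_modality[i]) &&
               inst$header_modality[i] == "OT") {
      reason <- "modality_OT"
    } else if (!(inst$readable[i] %in% TRUE)) {
      reason <- "unreadable_pixels"
    } else {
      px <- tryCatch(dicom_pixels(dicom_read(inst$file[i])),
                     error = function(e) NULL)
      if (is.null(px)) {
        reason <- "unreadable_pixels"
      } else {
        cls <- classify_report_image(px, cp)
        if (cls == "report") reason <- "pixel_screen"
      }
    }
    if (!is.null(reason)) {
      rows[[length(rows) + 1L]] <- data.frame(file = inst$file[i],
                                              reason = reason,
                                              stringsAsFactors = FALSE)
    }
  }
  rbind_all(rows, c("file", "reason"))
}

#' Classify an image as report or organ by its color spectrum
#'
#' Report iff BOTH hold after min-max scaling to 0-255: the background
#' fraction (share of pixels within `background_tolerance` of the full
#' range around the modal intensity) is at least `background_fraction`, AND
#' the distinct-intensity richness is at most `max_distinct_levels` 8-bit
#' levels. Text pages are near-binary with a dominant background; organ
#' depictions carry a broad, dense intensity spectrum. A degenerate
#' constant image is all background, hence a report.
#'
#' @param pixels 2-D numeric intensity matrix.
#' @param params thresholds list (`background_fraction`,
#'   `background_tolerance`, `max_distinct_levels`).
#' @return `"report"` or `"organ"`.
#' @export
classify_report_image <- function(pixels, params = NULL) {
  p <- params %||% list(background_fraction = 0.5, background_tolerance = 0.05,
                        max_distinct_levels = 64)
  v <- round(as.vector(scale_255(pixels)))
  tab <- table(v)
  mode_level <- as.numeric(names(tab)[which.max(tab)])
  tol <- (p$background_tolerance %||% 0.05) * 255
  bg_frac <- mean(abs(v - mode_level) <= tol)
  distinct <- length(tab)
  if (bg_frac >= (p$background_fraction %||% 0.5) &&
      distinct <= (p$max_distinct_levels %||% 64)) "report" else "organ"
}

#' Run the full de-identification audit over a repository
#'
#' @param index a `qc_repo_index`.
#' @param ruleset a `qc_ruleset` (its `deid` and `report_classifier` blocks
#'   are the profile).
#' @return object of class `qc_deid`: `violations` (file, category,
#'   detail), `candidates` (burnt-in screen output),
#'   `non_assessable` (unreadable files, counted separately).
#' @export
deid_audit <- function(index, ruleset = NULL) {
  rs <- ruleset %||% load_ruleset()
  inst <- index$instances
  profile <- rs$deid
  viol <- list()
  viol[[1]] <- audit_removed_attributes(inst, profile)
  pats <- unique(inst[c("provider", "patient_id")])
  for (i in seq_len(nrow(pats))) {
    sub <- inst[inst$provider == pats$provider[i] &
                  inst$patient_id == pats$patient_id[i], , drop = FALSE]
    viol[[length(viol) + 1L]] <- audit_date_hashing(sub, pats$patient_id[i],
                                                    profile)
  }
  cand <- screen_burnt_in_candidates(inst, rs$report_classifier)
  # candidates flagged by pixel content (or tagged burnt-in) are violations;
  # header-only suspicion is confirmed through the classifier
  for (i in seq_len(nrow(cand))) {
    f <- cand$file[i]
    confirmed <- if (cand$reason[i] %in% c("burned_in_annotation_tag",
                                           "pixel_screen")) TRUE else {
      px <- tryCatch(dicom_pixels(dicom_read(f)), error = function(e) NULL)
      !is.null(px) && classify_report_image(px, rs$report_classifier) == "report"
    }
    if (confirmed) {
      viol[[length(viol) + 1L]] <- data.frame(
        file = f, category = "burnt_in_report", detail = cand$reason[i],
        stringsAsFactors = FALSE)
    }
  }
  violations <- rbind_all(viol, c("file", "category", "detail"))
  non_assessable <- inst$file[!(inst$readable %in% TRUE)]
  structure(list(violations = violations, candidates = cand,
                 non_assessable = non_assessable),
            class = "qc_deid")
}

#' Anonymization conformance metric
#'
#' The record is each DICOM file; it fails iff it carries at least one
#' de-identification violation of any category. The percentage reported by
#' the metric is the conformant share (consistent with the other
#' dimensions); the non-conformant share is `100 - percentage`. Unreadable
#' files are excluded from the assessable denominator and reported
#' separately as non-assessable.
#'
#' @param index a `qc_repo_index`.
#' @param ruleset a `qc_ruleset`.
#' @param audit optionally a precomputed [deid_audit()] result.
#' @return list `metric` (a [qc_metric()], dimension `"anonymization"`),
#'   `audit` (the `qc_deid`), `non_assessable` (file count).
#' @export
anonymization_metric <- function(index, ruleset = NULL, audit = NULL) {
  rs <- ruleset %||% load_ruleset()
  aud <- audit %||% deid_audit(index, rs)
  inst <- index$instances
  assessable <- inst$file[inst$readable %in% TRUE]
  bad <- unique(aud$violations$file)
  flags <- data.frame(record = assessable,
                      pass = !(assessable %in% bad),
                      stringsAsFactors = FALSE)
  flags$reason <- ifelse(flags$pass, "", vapply(flags$record, function(f) {
    paste(unique(aud$violations$category[aud$violations$file == f]),
          collapse = ";")
  }, ""))
  list(metric = qc_metric("anonymization", flags),
       audit = aud, non_assessable = length(aud$non_assessable))
}

#' @export
print.qc_deid <- function(x, ...) {
  cat(sprintf("<qc_deid> %d violations on %d files (%d burnt-in candidates, %d non-assessable)\n",
              nrow(x$violations), length(unique(x$violations$file)),
              nrow(x$candidates), length(x$non_assessable)))
  if (nrow(x$violations) > 0) print(table(x$violations$category))
  invisible(x)
}
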
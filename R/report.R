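# Pipeline orchestration and the structured quality report.
#
# The report is advisory by design: the exit semantics of the CLI are
# "ran / did not run", never "data good / data bad" (a --fail-below gate is
# available for CI usage). The report carries no wall-clock timestamps, so
# reruns on identical input and configuration are byte-identical.

PIPELINE_STAGES <- c("clinical", "fairness", "dedup", "annotation",
                     "profile", "deid")

#' Run the full quality pipeline over a repository
#'
#' Stages run in dependency order (scan, then clinical metrics, fairness,
#' imaging stages); a failure inside one stage is recorded in the run log
#' and does not abort the others. Stage selection controls cost: the dedup
#' stage is pixel-heavy and can be skipped for metadata-only audits.
#'
#' @param root repository root directory.
#' @param ruleset a `qc_ruleset`, or a path to one, or `NULL` for the
#'   shipped default.
#' @param stages character vector of stages to run (subset of
#'   `clinical`, `fairness`, `dedup`, `annotation`, `profile`, `deid`).
#' @param dedup_grade similarity grade for the dedup stage.
#' @return object of class `qc_report`.
#' @export
run_pipeline <- function(root, ruleset = NULL,
                         stages = PIPELINE_STAGES,
                         dedup_grade = "high") {
  if (length(stages) == 0) stopf("no stages selected")
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  rs <- if (is.character(ruleset)) load_ruleset(ruleset) else
    ruleset %||% load_ruleset()

  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note("stage %s failed: %s", name, conditionMessage(e))
      NULL
    })
  }

  index <- scan_repository(root, rs)
  log <- c(log, index$warnings)
  clinical <- run_stage("load_clinical", load_clinical_tables(root, rs))
  cancer_by_patient <- if (!is.null(clinical) && nrow(clinical) > 0)
    setNames(clinical$cancer_type, clinical$patient_id) else NULL

  report <- list(
    toolkit_version = as.character(utils::packageVersion("cimqc")),
    ruleset_digest = ruleset_digest(rs),
    root = basename(root),
    stages_run = stages,
    index_summary = list(
      providers = length(unique(index$patients$provider)),
      patients = nrow(index$patients),
      series = nrow(index$series),
      instances = nrow(index$instances),
      masks = nrow(index$annotations),
      skipped_files = nrow(index$skipped)),
    metrics = list(), fairness = NULL, dedup = NULL,
    annotation = NULL, profiles = NULL, deid = NULL,
    not_run = setdiff(PIPELINE_STAGES, stages))

  if ("clinical" %in% stages && !is.null(clinical) && nrow(clinical) > 0) {
    report$metrics$completeness <- run_stage("completeness",
      metric_to_list(completeness(clinical, index, rs)))
    report$metrics$validity <- run_stage("validity",
      metric_to_list(validity(clinical, rs)))
    report$metrics$consistency <- run_stage("consistency",
      metric_to_list(suppressWarnings(consistency(clinical, rs))))
    report$metrics$integrity <- run_stage("integrity",
      metric_to_list(integrity(clinical, index, rs)))
  }
  if ("fairness" %in% stages && !is.null(clinical) && nrow(clinical) > 0) {
    fr <- run_stage("fairness", fairness_report(clinical, rs))
    if (!is.null(fr)) {
      report$fairness <- list(cells = fr$long, flags = fr$flags)
    }
  }
  if ("dedup" %in% stages) {
    report$dedup <- run_stage("dedup", {
      uidg <- uid_screen(index)
      intra <- intra_scan_all(index, grade = dedup_grade, ruleset = rs)
      inter_all <- lapply(sort_c(unique(index$patients$provider)), function(pr)
        inter_patient_scan(index, pr, grade = dedup_grade, ruleset = rs))
      inter_pairs <- do.call(rbind, lapply(inter_all, `[[`, "pairs"))
      list(
        uid_groups = length(uidg),
        uid_cross_modality = sum(vapply(uidg, `[[`, TRUE, "cross_modality")),
        grade = dedup_grade,
        intra = list(pairs = intra$n_comparisons, flagged = intra$n_flagged,
                     by_modality = summarize_by_modality(intra),
                     by_gap = stratify_by_timepoint_gap(intra)),
        inter = list(pairs = if (is.null(inter_pairs)) 0L else nrow(inter_pairs),
                     flagged = if (is.null(inter_pairs)) 0L else
                       sum(inter_pairs$flagged)))
    })
  }
  if ("annotation" %in% stages) {
    ann <- run_stage("annotation", {
      ac <- annotation_consistency(index)
      cov <- timepoint_coverage(index, cancer_by_patient)
      list(consistency = metric_to_list(ac$metric),
           empty_pct = ac$empty_pct,
           n_empty = sum(ac$empty$empty),
           n_orphans = nrow(ac$orphans),
           coverage = cov)
    })
    if (!is.null(ann)) {
      report$metrics$annotation_consistency <- ann$consistency
      report$annotation <- ann
    }
  }
  if ("profile" %in% stages) {
    report$profiles <- run_stage("profile", {
      at <- extract_attributes(index, rs, cancer_by_patient)
      profile_attributes(at, rs)
    })
  }
  if ("deid" %in% stages) {
    am <- run_stage("deid", anonymization_metric(index, rs))
    if (!is.null(am)) {
      report$metrics$anonymization <- metric_to_list(am$metric)
      report$deid <- list(
        violations_by_category =
          as.list(table(am$audit$violations$category)),
        n_violating_files = length(unique(am$audit$violations$file)),
        n_burnt_in_candidates = nrow(am$audit$candidates),
        non_assessable = am$non_assessable,
        nonconformant_pct = if (is.na(am$metric$percentage)) NULL else
          round_half_up(100 - am$metric$percentage))
    }
  }
  report$run_log <- log
  structure(report, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  s <- x$index_summary
  cat(sprintf("  %d providers / %d patients / %d series / %d instances\n",
              s$providers, s$patients, s$series, s$instances))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    pc <- if (is.null(m$percentage)) "undefined" else sprintf("%.2f%%", m$percentage)
    cat(sprintf("  %-24s %s (%d/%d)\n", nm, pc, m$numerator, m$denominator))
  }
  if (!is.null(x$dedup))
    cat(sprintf("  dedup: %d UID groups; intra %d/%d flagged; inter %d/%d flagged\n",
                x$dedup$uid_groups, x$dedup$intra$flagged, x$dedup$intra$pairs,
                x$dedup$inter$flagged, x$dedup$inter$pairs))
  if (length(x$run_log) > 0)
    cat(sprintf("  %d log entries\n", length(x$run_log)))
  invisible(x)
}

#' Write a quality report
#'
#' @param report a `qc_report`.
#' @param out output path: a `.json` file for `format = "json"`, a text
#'   file for `"text"`, or a directory for `"csv"` (one CSV per tabular
#'   block).
#' @param format one of `"json"`, `"text"`, `"csv"`.
#' @return paths written, invisibly.
#' @export
write_report <- function(report, out, format = c("json", "text", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows", null = "null")
    return(invisible(out))
  }
  if (format == "text") {
    con <- file(out, "w"); on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
    return(invisible(out))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    if (is.null(df) || !is.data.frame(df) || nrow(df) == 0) return()
    f <- file.path(out, paste0(name, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    paths <<- c(paths, f)
  }
  mdf <- do.call(rbind, lapply(names(report$metrics), function(nm) {
    m <- report$metrics[[nm]]
    data.frame(dimension = nm, numerator = m$numerator,
               denominator = m$denominator,
               percentage = m$percentage %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  wr(mdf, "metrics")
  wr(report$fairness$cells, "fairness_distributions")
  wr(report$fairness$flags, "fairness_flags")
  wr(report$annotation$coverage, "annotation_timepoint_coverage")
  wr(report$profiles, "dicom_attribute_profiles")
  wr(report$dedup$intra$by_modality, "dedup_intra_by_modality")
  wr(report$dedup$intra$by_gap, "dedup_intra_by_timepoint_gap")
  invisible(paths)
}

#' Validate a report against the shipped schema
#'
#' Lightweight structural validation: required blocks present with the
#' expected types, and every metric block carrying integer
#' numerator/denominator. The JSON schema itself is shipped at
#' `inst/extdata/report_schema.json` for external validators.
#'
#' @param report a `qc_report` or a path to a report JSON file.
#' @return character vector of problems; empty iff valid.
#' @export
validate_report <- function(report) {
  x <- if (is.character(report)) jsonlite::read_json(report) else unclass(report)
  problems <- character()
  req <- c("toolkit_version", "ruleset_digest", "index_summary",
           "metrics", "stages_run")
  for (f in req) if (is.null(x[[f]]))
    problems <- c(problems, sprintf("missing required field: %s", f))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    for (f in c("numerator", "denominator")) {
      if (is.null(m[[f]]) || !is.numeric(m[[f]]) || m[[f]] < 0)
        problems <- c(problems,
                      sprintf("metrics/%s/%s missing or negative", nm, f))
    }
    if (!is.null(m$numerator) && !is.null(m$denominator) &&
        is.numeric(m$numerator) && is.numeric(m$denominator) &&
        m$numerator > m$denominator)
      problems <- c(problems, sprintf("metrics/%s: numerator > denominator", nm))
  }
  problems
}
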
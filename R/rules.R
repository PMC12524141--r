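# Rule-set loading and validation.
#
# Every quality dimension is parameterized by one machine-readable rule-set:
# mandatory fields, per-field value rules, cross-link rules, label
# vocabularies, the de-identification profile, dedup thresholds and fairness
# binning. The shipped default lives in inst/extdata/default_rules.yaml.

#' Load a quality rule-set
#'
#' Reads a YAML or JSON rule-set, applies documented defaults for omitted
#' optional blocks, and validates its internal invariants. Any invariant
#' violation is fatal and names the offending field path.
#'
#' @param config_path path to a `.yaml`/`.yml` or `.json` rule-set; `NULL`
#'   loads the shipped default.
#' @return object of class `qc_ruleset`.
#' @export
load_ruleset <- function(config_path = NULL) {
  if (is.null(config_path)) {
    config_path <- system.file("extdata", "default_rules.yaml", package = "cimqc")
  }
  if (!file.exists(config_path)) stopf("rule-set file not found: %s", config_path)
  rs <- if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(config_path)
  }
  rs <- apply_ruleset_defaults(rs)
  class(rs) <- "qc_ruleset"
  defects <- check_ruleset(rs)
  if (length(defects) > 0) {
    stopf("invalid rule-set %s:\n  %s", config_path,
          paste(defects, collapse = "\n  "))
  }
  rs
}

apply_ruleset_defaults <- function(rs) {
  rs$missing_sentinels <- rs$missing_sentinels %||% c("", "na", "n/a", "null")
  rs$layout <- rs$layout %||% list()
  rs$layout$timepoint_pattern <- rs$layout$timepoint_pattern %||% "^T([0-9]+)$"
  rs$layout$mask_suffix <- rs$layout$mask_suffix %||% "_annotation"
  rs$modality_codes <- rs$modality_codes %||%
    c("CT", "MR", "MG", "US", "PT", "FUSCT", "FUSPT", "XRAY")
  rs$integrity <- rs$integrity %||% list()
  rs$integrity$include_declared_absent <- rs$integrity$include_declared_absent %||% TRUE
  rs$dedup <- rs$dedup %||% list()
  rs$dedup$thresholds <- rs$dedup$thresholds %||% list(high = 0.1, normal = 10.0)
  rs$dedup$resample_size <- rs$dedup$resample_size %||% 64L
  rs$dedup$cross_pair_cap <- rs$dedup$cross_pair_cap %||% 200L
  rs$fairness <- rs$fairness %||% list()
  rs$fairness$variables <- rs$fairness$variables %||%
    c("sex", "age_bin", "cancer_type", "cancer_grade")
  rs$fairness$age_bin <- rs$fairness$age_bin %||% list(start = 20, end = 95, width = 5)
  rs$fairness$dominance_share <- rs$fairness$dominance_share %||% 0.8
  rs$report_classifier <- rs$report_classifier %||% list()
  rs$report_classifier$background_fraction <-
    rs$report_classifier$background_fraction %||% 0.5
  rs$report_classifier$background_tolerance <-
    rs$report_classifier$background_tolerance %||% 0.05
  rs$report_classifier$max_distinct_levels <-
    rs$report_classifier$max_distinct_levels %||% 64L
  rs$categorical_other_floor <- rs$categorical_other_floor %||% 0.05
  rs$modality_declarations <- rs$modality_declarations %||%
    list(column_pattern = "^modalities_t([0-9]+)$", separator = ";")
  rs
}

#' Check rule-set invariants
#'
#' Returns a character vector of defects (empty when the rule-set is valid):
#' every mandatory field must have a field rule, label codes must be positive
#' integers, the "high" dedup threshold must lie below "normal", cross-link
#' rules must reference known fields, and every annotated (cancer, modality)
#' pair must resolve to a label vocabulary. Defects are returned, not raised.
#'
#' @param ruleset a `qc_ruleset`.
#' @return character vector of defect descriptions; empty iff valid.
#' @export
check_ruleset <- function(ruleset) {
  rs <- ruleset
  defects <- character()
  fr_names <- names(rs$field_rules)
  for (ct in names(rs$mandatory_fields)) {
    miss <- setdiff(unlist(rs$mandatory_fields[[ct]]), fr_names)
    if (length(miss) > 0) {
      defects <- c(defects, sprintf(
        "mandatory_fields/%s: field(s) %s missing from field_rules",
        ct, paste(miss, collapse = ", ")))
    }
  }
  thr <- rs$dedup$thresholds
  if (!is.null(thr$high) && !is.null(thr$normal) && thr$high >= thr$normal) {
    defects <- c(defects, sprintf(
      "dedup/thresholds: high (%s) must be below normal (%s)", thr$high, thr$normal))
  }
  for (i in seq_along(rs$crosslink_rules)) {
    rule <- rs$crosslink_rules[[i]]
    refs <- c(rule$condition_field, unlist(rule$require_missing),
              unlist(rule$require_present), names(rule$require_equals))
    unknown <- setdiff(refs, fr_names)
    if (length(unknown) > 0) {
      defects <- c(defects, sprintf(
        "crosslink_rules[%d] (%s): unknown field(s) %s", i,
        rule$name %||% "unnamed", paste(unknown, collapse = ", ")))
    }
  }
  for (ct in names(rs$annotated_modalities)) {
    for (mod in unlist(rs$annotated_modalities[[ct]])) {
      if (is.null(lookup_vocabulary(rs, ct, mod))) {
        defects <- c(defects, sprintf(
          "label_vocabulary: no vocabulary for %s/%s and no default", ct, mod))
      }
    }
  }
  codes <- vocab_codes(rs)
  bad <- codes[!(codes == floor(codes) & codes > 0)]
  if (length(bad) > 0) {
    defects <- c(defects, sprintf(
      "label_vocabulary: label codes must be positive integers (found %s)",
      paste(unique(bad), collapse = ", ")))
  }
  defects
}

# all label codes appearing anywhere in the vocabulary tree
vocab_codes <- function(rs) {
  out <- numeric()
  walk <- function(x) {
    if (is.list(x) && !is.null(x$code)) {
      out <<- c(out, as.numeric(x$code))
    } else if (is.list(x)) {
      lapply(x, walk)
    }
  }
  walk(rs$label_vocabulary)
  out
}

#' Resolve the label vocabulary for a (cancer type, modality) pair
#'
#' Lookup order: cancer-specific modality entry, then the shipped `default`
#' scheme. Returns `NULL` when nothing applies.
#'
#' @param ruleset a `qc_ruleset`.
#' @param cancer_type cancer type name.
#' @param modality modality code.
#' @return list of entries `{code, name, class}` or `NULL`.
#' @export
lookup_vocabulary <- function(ruleset, cancer_type, modality) {
  v <- ruleset$label_vocabulary
  if (is.null(v)) return(NULL)
  specific <- v[[cancer_type]][[modality]]
  if (!is.null(specific)) return(specific)
  v$default
}

#' Serialize a rule-set back to YAML
#'
#' `load_ruleset(save_ruleset(rs, f))` is idempotent: the reloaded rule-set
#' is identical to the saved one.
#'
#' @param ruleset a `qc_ruleset`.
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
save_ruleset <- function(ruleset, path) {
  x <- unclass(ruleset)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.qc_ruleset <- function(x, ...) {
  cat("<qc_ruleset>\n")
  cat(sprintf("  cancer types: %s\n", paste(unlist(x$cancer_types), collapse = ", ")))
  cat(sprintf("  field rules: %d; crosslink rules: %d\n",
              length(x$field_rules), length(x$crosslink_rules)))
  cat(sprintf("  dedup thresholds: high %s / normal %s\n",
              x$dedup$thresholds$high, x$dedup$thresholds$normal))
  cat(sprintf("  de-id forbidden attributes: %s\n",
              paste(unlist(x$deid$forbidden_attributes), collapse = ", ")))
  invisible(x)
}

# digest of the rule-set for report provenance (content hash of canonical yaml)
ruleset_digest <- function(ruleset) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  save_ruleset(ruleset, f)
  unname(tools::md5sum(f))
}
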
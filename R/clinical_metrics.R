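# Rule-based clinical-metadata quality dimensions.
#
# Record definitions follow the dimension ledger:
#   completeness - record = patient
#   validity     - record = each inserted (non-missing) value in a
#                  rule-covered field; missing values belong to completeness
#   consistency  - record = each applicable cross-link rule evaluation per
#                  patient
#   integrity    - record = each provided modality occurrence per
#                  (patient, timepoint), plus declared-but-absent modalities

mandatory_for <- function(rs, cancer_type) {
  mf <- rs$mandatory_fields
  if (!is.null(cancer_type) && !is.na(cancer_type) && !is.null(mf[[cancer_type]]))
    return(unlist(mf[[cancer_type]]))
  if (!is.null(mf$default)) return(unlist(mf$default))
  unique(unlist(mf))
}

#' Completeness of clinical records
#'
#' A patient (the record) is complete iff all mandatory fields for their
#' cancer type are non-missing AND the repository index shows at least one
#' imaging modality at a timepoint beyond diagnosis (timepoint > 1).
#' Patients present in the table but absent from the index fail the
#' follow-up condition with a dedicated reason code.
#'
#' @param table a `qc_clinical` table.
#' @param index a `qc_repo_index`.
#' @param ruleset a `qc_ruleset`.
#' @return a [qc_metric()] for dimension `"completeness"`.
#' @export
completeness <- function(table, index, ruleset) {
  rs <- ruleset
  has_followup <- unique(index$series$patient_id[
    !is.na(index$series$timepoint) & index$series$timepoint > 1])
  indexed <- unique(index$patients$patient_id)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    pid <- table$patient_id[i]
    mand <- mandatory_for(rs, table$cancer_type[i])
    present <- vapply(mand, function(f)
      f %in% names(table) && !is.na(table[[f]][i]), TRUE)
    reasons <- character()
    if (any(!present))
      reasons <- paste0("missing:", mand[!present])
    if (!(pid %in% has_followup)) {
      reasons <- c(reasons, if (pid %in% indexed) "no_followup_timepoint"
                   else "patient_not_in_index")
    }
    data.frame(record = pid, pass = length(reasons) == 0,
               reason = paste(reasons, collapse = ";"), stringsAsFactors = FALSE)
  })
  qc_metric("completeness", do.call(rbind, rows))
}

check_field_value <- function(rule, value) {
  type <- rule$type %||% "free-text"
  if (type == "free-text") return(TRUE)
  if (type == "categorical") return(value %in% unlist(rule$allowed))
  if (type %in% c("integer", "real")) {
    pat <- if (type == "integer") "^-?[0-9]+$" else
      "^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$"
    if (!grepl(pat, trimws(value))) return(FALSE)
    x <- as.numeric(value)
    if (!is.null(rule$min) && x < rule$min) return(FALSE)
    if (!is.null(rule$max) && x > rule$max) return(FALSE)
    return(TRUE)
  }
  if (type == "date") {
    pat <- rule$pattern %||% "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"
    return(grepl(pat, value) &&
             !is.na(as.Date(value, format = rule$format %||% "%Y-%m-%d")))
  }
  TRUE
}

#' Validity of inserted clinical values
#'
#' The record is each non-missing value in a rule-covered field; it passes
#' iff type, format and range/allowed-set all hold. Missing values are not
#' in the denominator (they are completeness's concern), so a value like
#' stage "3" against the allowed set {I, II, III, IV} is invalid while an
#' empty stage is not counted here at all.
#'
#' @inheritParams completeness
#' @return a [qc_metric()] for dimension `"validity"`.
#' @export
validity <- function(table, ruleset) {
  rules <- ruleset$field_rules
  fields <- intersect(names(rules), names(table))
  rows <- list()
  for (f in fields) {
    vals <- table[[f]]
    ok_idx <- which(!is.na(vals))
    for (i in ok_idx) {
      pass <- check_field_value(rules[[f]], vals[i])
      rows[[length(rows) + 1L]] <- data.frame(
        record = paste0(table$patient_id[i], ":", f),
        pass = pass,
        reason = if (pass) "" else paste0("invalid:", f),
        stringsAsFactors = FALSE)
    }
  }
  qc_metric("validity", rbind_all(rows, c("record", "pass", "reason")))
}

eval_crosslink <- function(rule, row) {
  cond <- row[[rule$condition_field]]
  if (is.null(cond) || is.na(cond)) return(NA)  # not applicable
  triggered <- if (!is.null(rule$condition_equals))
    identical(as.character(cond), as.character(rule$condition_equals)) else TRUE
  if (!triggered) return(TRUE)
  for (f in unlist(rule$require_missing)) {
    if (!is.null(row[[f]]) && !is.na(row[[f]])) return(FALSE)
  }
  for (f in unlist(rule$require_present)) {
    if (is.null(row[[f]]) || is.na(row[[f]])) return(FALSE)
  }
  for (f in names(rule$require_equals)) {
    if (is.null(row[[f]]) || is.na(row[[f]]) ||
        !identical(as.character(row[[f]]),
                   as.character(rule$require_equals[[f]]))) return(FALSE)
  }
  TRUE
}

#' Consistency of cross-linked clinical information
#'
#' Evaluates every configured cross-link rule per patient. A rule is
#' applicable when its condition field is non-missing; the record passes iff
#' the rule's requirement holds (e.g. biomarker fields must be empty when
#' the biopsy field says "No Biopsy"). With no cross-link rules configured
#' the result is vacuous-undefined and a warning is emitted.
#'
#' @inheritParams completeness
#' @return a [qc_metric()] for dimension `"consistency"`.
#' @export
consistency <- function(table, ruleset) {
  rules <- ruleset$crosslink_rules
  if (length(rules) == 0) {
    warnf("no crosslink rules configured; consistency is undefined")
    return(qc_metric("consistency", NULL))
  }
  rows <- list()
  for (i in seq_len(nrow(table))) {
    row <- as.list(table[i, , drop = FALSE])
    for (k in seq_along(rules)) {
      res <- eval_crosslink(rules[[k]], row)
      if (is.na(res)) next
      nm <- rules[[k]]$name %||% paste0("rule", k)
      rows[[length(rows) + 1L]] <- data.frame(
        record = paste0(table$patient_id[i], ":", nm),
        pass = res,
        reason = if (res) "" else paste0("crosslink:", nm),
        stringsAsFactors = FALSE)
    }
  }
  qc_metric("consistency", rbind_all(rows, c("record", "pass", "reason")))
}

# parse "CT;CT;MG" declaration cells into a named count vector
parse_declaration <- function(x, sep = ";") {
  if (is.null(x) || is.na(x) || trimws(x) == "") return(integer(0))
  parts <- trimws(strsplit(x, sep, fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  if (length(parts) == 0) return(integer(0))
  tab <- table(toupper(parts))
  setNames(as.integer(tab), names(tab))
}

#' Integrity of image-to-metadata linkage
#'
#' The record is each modality occurrence at each (patient, timepoint). A
#' provided modality passes iff (a) it is declared in the clinical template
#' for that timepoint, (b) the declared series count equals the provided
#' series count, and (c) its directories satisfy the naming convention.
#' Declared-but-absent modalities add failing records (switchable via
#' `integrity$include_declared_absent` in the rule-set).
#'
#' @inheritParams completeness
#' @return a [qc_metric()] for dimension `"integrity"`.
#' @export
integrity <- function(table, index, ruleset) {
  rs <- ruleset
  decl_pat <- rs$modality_declarations$column_pattern
  sep <- rs$modality_declarations$separator %||% ";"
  decl_cols <- grep(decl_pat, names(table), value = TRUE)
  decl_tp <- as.integer(sub(decl_pat, "\\1", decl_cols))

  ser <- index$series
  rows <- list()
  add <- function(pid, tp, mod, pass, reason) {
    rows[[length(rows) + 1L]] <<- data.frame(
      record = paste0(pid, ":T", tp, ":", mod), pass = pass,
      reason = reason, stringsAsFactors = FALSE)
  }

  pids <- unique(c(table$patient_id, ser$patient_id))
  for (pid in sort_c(pids)) {
    ti <- which(table$patient_id == pid)
    ps <- ser[ser$patient_id == pid, , drop = FALSE]
    tps <- sort(unique(c(if (length(ti) == 1) decl_tp else integer(0),
                         ps$timepoint)))
    tps <- tps[!is.na(tps)]
    for (tp in tps) {
      declared <- if (length(ti) == 1 && tp %in% decl_tp) {
        parse_declaration(table[[decl_cols[match(tp, decl_tp)]]][ti], sep)
      } else integer(0)
      pst <- ps[!is.na(ps$timepoint) & ps$timepoint == tp, , drop = FALSE]
      provided <- table(pst$modality[!is.na(pst$modality)])
      mods <- sort_c(unique(c(names(declared), names(provided))))
      for (mod in mods) {
        d <- declared[mod]; d <- if (is.na(d)) 0L else as.integer(d)
        v <- provided[mod]; v <- if (is.na(v)) 0L else as.integer(v)
        if (v > 0) {
          reasons <- character()
          if (d == 0) reasons <- "undeclared_modality"
          else if (d != v) reasons <- "count_mismatch"
          mod_rows <- which(!is.na(pst$modality) & pst$modality == mod)
          if (!all(pst$naming_ok[mod_rows] %in% TRUE))
            reasons <- c(reasons, "naming_violation")
          add(pid, tp, mod, length(reasons) == 0,
              paste(reasons, collapse = ";"))
        } else if (d > 0 && isTRUE(rs$integrity$include_declared_absent)) {
          add(pid, tp, mod, FALSE, "declared_modality_absent")
        }
      }
    }
  }
  qc_metric("integrity", rbind_all(rows, c("record", "pass", "reason")))
}
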
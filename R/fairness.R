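# Subgroup fairness profiling.
#
# Fairness here is balanced per-site representation of sex, age bin, cancer
# type and cancer grade, reported as normalized class percentages (the
# repository's tables normalize over reported cases, so missing values are
# excluded from denominators and the missing rate is reported alongside).
# No scalar fairness index is computed: the deliverable is the distribution
# plus threshold flags.

#' Assign an age to its 5-year bin
#'
#' Bins are left-open right-closed intervals `(20, 25]` ... `(90, 95]`, with
#' overflow bins `<=20` and `>95`. Negative ages are a validity concern and
#' return `NA` with a warning.
#'
#' @param age numeric vector of ages in years.
#' @param edges list with `start`, `end`, `width` (defaults 20, 95, 5).
#' @return character vector of bin labels.
#' @export
assign_age_bin <- function(age, edges = list(start = 20, end = 95, width = 5)) {
  age <- suppressWarnings(as.numeric(age))
  lo <- edges$start %||% 20; hi <- edges$end %||% 95; w <- edges$width %||% 5
  out <- character(length(age))
  neg <- !is.na(age) & age < 0
  if (any(neg)) {
    warnf("%d negative age(s) excluded from binning", sum(neg))
  }
  for (i in seq_along(age)) {
    a <- age[i]
    out[i] <- if (is.na(a) || a < 0) NA_character_
    else if (a <= lo) sprintf("<=%d", lo)
    else if (a > hi) sprintf(">%d", hi)
    else {
      k <- ceiling((a - lo) / w)
      sprintf("(%d, %d]", lo + (k - 1) * w, lo + k * w)
    }
  }
  out
}

age_bin_levels <- function(edges = list(start = 20, end = 95, width = 5)) {
  lo <- edges$start %||% 20; hi <- edges$end %||% 95; w <- edges$width %||% 5
  starts <- seq(lo, hi - w, by = w)
  c(sprintf("<=%d", lo), sprintf("(%d, %d]", starts, starts + w), sprintf(">%d", hi))
}

fairness_column <- function(variable) {
  switch(variable,
         sex = "sex", age_bin = "age", cancer_type = "cancer_type",
         cancer_grade = "grade",
         stopf("unknown fairness variable: %s", variable))
}

fairness_levels <- function(rs, variable, table) {
  if (variable == "age_bin") return(age_bin_levels(rs$fairness$age_bin))
  if (variable == "sex") return(unlist(rs$field_rules$sex$allowed) %||% c("M", "F"))
  if (variable == "cancer_grade") {
    cts <- unique(table$cancer_type[!is.na(table$cancer_type)])
    gl <- rs$fairness$grade_levels
    lv <- unique(unlist(lapply(cts, function(ct) gl[[ct]] %||% gl$default)))
    return(as.character(sort(lv %||% 1:3)))
  }
  NULL  # open class set: observed values
}

#' Normalized subgroup distribution at one site
#'
#' Computes the class counts and normalized percentages (half-up, 2
#' decimals) of one fairness variable for one provider. The denominator is
#' the number of patients at that site with the variable non-missing; the
#' missing rate is reported alongside. Closed class sets (age bins, sex,
#' grades) list zero-count classes explicitly.
#'
#' @param table a `qc_clinical` table.
#' @param variable one of `"sex"`, `"age_bin"`, `"cancer_type"`,
#'   `"cancer_grade"`.
#' @param site provider id (matched against the `provider` column); `NULL`
#'   pools all sites.
#' @param ruleset a `qc_ruleset`.
#' @return object of class `qc_distribution`: data.frame `classes`
#'   (class, count, percentage), `n`, `n_missing`, `variable`, `site`.
#' @export
subgroup_distribution <- function(table, variable, site = NULL, ruleset = NULL) {
  rs <- ruleset %||% load_ruleset()
  sub <- if (is.null(site)) table else table[
    !is.na(table$provider) & table$provider == site, , drop = FALSE]
  col <- fairness_column(variable)
  vals <- if (col %in% names(sub)) sub[[col]] else rep(NA_character_, nrow(sub))
  if (variable == "age_bin") vals <- assign_age_bin(vals, rs$fairness$age_bin)
  n_missing <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  levels <- fairness_levels(rs, variable, table)
  if (is.null(levels)) levels <- sort_c(unique(as.character(vals)))
  counts <- table(factor(as.character(vals), levels = levels))
  n <- length(vals)
  classes <- data.frame(class = names(counts), count = as.integer(counts),
                        percentage = vapply(as.integer(counts), function(k)
                          pct_of(k, n), 0), stringsAsFactors = FALSE)
  structure(list(variable = variable, site = site %||% "all",
                 classes = classes, n = n, n_missing = n_missing),
            class = "qc_distribution")
}

#' @export
print.qc_distribution <- function(x, ...) {
  cat(sprintf("<qc_distribution> %s @ %s (n = %d, %d missing)\n",
              x$variable, x$site, x$n, x$n_missing))
  for (i in seq_len(nrow(x$classes))) {
    pc <- x$classes$percentage[i]
    cat(sprintf("  %-12s %4d  %s\n", x$classes$class[i], x$classes$count[i],
                if (is.na(pc)) "-" else sprintf("%6.2f%%", pc)))
  }
  invisible(x)
}

#' Full fairness report
#'
#' Computes per-site normalized distributions for all configured fairness
#' variables and flags representation problems: absent subgroups within a
#' closed class set, dominance of one class above the configured share
#' (default 0.8), and sites missing a variable entirely. Variables marked
#' structurally fixed for a cancer type (e.g. sex in prostate cancer) are
#' not flagged for single-class dominance.
#'
#' @param table a `qc_clinical` table.
#' @param ruleset a `qc_ruleset`.
#' @return object of class `qc_fairness`: `distributions` (list),
#'   `flags` (data.frame: site, variable, flag, detail), `long`
#'   (long-format data.frame of all cells).
#' @export
fairness_report <- function(table, ruleset = NULL) {
  rs <- ruleset %||% load_ruleset()
  sites <- sort_c(unique(table$provider[!is.na(table$provider)]))
  if (length(sites) == 0) sites <- "all"
  vars <- unlist(rs$fairness$variables)
  share <- rs$fairness$dominance_share %||% 0.8
  dists <- list(); flags <- list(); long <- list()
  for (s in sites) {
    cts <- unique(table$cancer_type[!is.na(table$provider) &
                                      table$provider == s])
    fixed <- unique(unlist(rs$fairness$structurally_fixed[
      cts[!is.na(cts)]]))
    for (v in vars) {
      d <- subgroup_distribution(table, v, site = if (identical(s, "all")) NULL else s,
                                 ruleset = rs)
      key <- paste(s, v, sep = ":")
      dists[[key]] <- d
      long[[key]] <- cbind(site = s, variable = v, d$classes,
                           stringsAsFactors = FALSE)
      if (d$n == 0) {
        flags[[length(flags) + 1L]] <- data.frame(
          site = s, variable = v, flag = "variable_missing",
          detail = sprintf("no non-missing %s values", v),
          stringsAsFactors = FALSE)
        next
      }
      zero <- d$classes$class[d$classes$count == 0]
      closed <- !is.null(fairness_levels(rs, v, table))
      if (closed && length(zero) > 0 && !(v %in% fixed)) {
        flags[[length(flags) + 1L]] <- data.frame(
          site = s, variable = v, flag = "absent_subgroup",
          detail = paste(zero, collapse = ","), stringsAsFactors = FALSE)
      }
      dom <- d$classes[d$classes$count / d$n > share, , drop = FALSE]
      if (nrow(dom) > 0 && !(v %in% fixed)) {
        flags[[length(flags) + 1L]] <- data.frame(
          site = s, variable = v, flag = "dominance",
          detail = sprintf("%s (%.2f%%)", dom$class[1], dom$percentage[1]),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(distributions = dists,
                 flags = rbind_all(flags, c("site", "variable", "flag", "detail")),
                 long = if (length(long) == 0) data.frame() else
                   do.call(rbind, c(long, list(make.row.names = FALSE)))),
            class = "qc_fairness")
}

#' @export
print.qc_fairness <- function(x, ...) {
  cat(sprintf("<qc_fairness> %d distributions, %d flags\n",
              length(x$distributions), nrow(x$flags)))
  if (nrow(x$flags) > 0) print(utils::head(x$flags, 20))
  invisible(x)
}
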
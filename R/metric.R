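#' Quality-dimension metric result
#'
#' Container for one quality dimension: a per-record pass/fail ledger plus the
#' aggregate numerator/denominator/percentage. Every dimension (completeness,
#' validity, consistency, integrity, anonymization, annotation consistency)
#' reports through this shape so that the quality report is uniform.
#'
#' The percentage is the share of *passing* records, rounded half-up to two
#' decimals. A zero denominator yields an undefined (`NA`) percentage, never
#' 0 or 100.
#'
#' @param dimension name of the quality dimension.
#' @param flags data.frame with columns `record` (identifier), `pass`
#'   (logical) and `reason` (character; `""` for passing records).
#' @return object of class `qc_metric` with fields `dimension`, `numerator`,
#'   `denominator`, `percentage` and `flags`.
#' @export
qc_metric <- function(dimension, flags) {
  if (is.null(flags) || nrow(flags) == 0) {
    flags <- data.frame(record = character(), pass = logical(),
                        reason = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("record", "pass", "reason") %in% names(flags)))
  num <- sum(flags$pass)
  den <- nrow(flags)
  structure(
    list(dimension = dimension,
         numerator = num,
         denominator = den,
         percentage = pct_of(num, den),
         flags = flags),
    class = "qc_metric")
}

#' @export
print.qc_metric <- function(x, ...) {
  pc <- if (is.na(x$percentage)) "undefined (no records)" else
    sprintf("%.2f%%", x$percentage)
  cat(sprintf("<qc_metric> %s: %s (%d/%d records pass)\n",
              x$dimension, pc, x$numerator, x$denominator))
  fails <- x$flags[!x$flags$pass, , drop = FALSE]
  if (nrow(fails) > 0) {
    tab <- sort(table(fails$reason), decreasing = TRUE)
    for (i in seq_along(tab)) {
      cat(sprintf("  %-40s %d\n", names(tab)[i], tab[[i]]))
    }
  }
  invisible(x)
}

#' @export
format.qc_metric <- function(x, ...) {
  pc <- if (is.na(x$percentage)) "NA" else sprintf("%.2f", x$percentage)
  sprintf("%s: %s%% (%d/%d)", x$dimension, pc, x$numerator, x$denominator)
}

# serialize for the JSON report
metric_to_list <- function(m) {
  list(dimension = m$dimension,
       numerator = m$numerator,
       denominator = m$denominator,
       percentage = if (is.na(m$percentage)) NULL else m$percentage,
       n_failing = m$denominator - m$numerator)
}
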
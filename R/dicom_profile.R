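# Acquisition-attribute profiling (sampling-bias diagnostics).
#
# Numeric attributes are summarized as median [Q1 Q3]; categorical
# attributes as normalized shares. Quartiles use linear interpolation
# between order statistics (the common "type 7" convention; switchable to
# nearest-rank), since different vendors, kernels and voxel geometries are
# exactly the kind of site effect that biases downstream models.

ATTRIBUTE_COLUMNS <- c(
  slice_thickness = "slice_thickness",
  pixel_spacing = "pixel_spacing_row",
  rows = "rows",
  columns = "cols",
  convolution_kernel = "convolution_kernel",
  manufacturer = "manufacturer",
  magnetic_field_strength = "field_strength",
  scanning_sequence = "scanning_sequence")

NUMERIC_ATTRIBUTES <- c("slice_thickness", "pixel_spacing", "rows", "columns",
                        "magnetic_field_strength")

#' Extract acquisition attributes per instance
#'
#' Applies the per-modality attribute spec from the rule-set (CT: slice
#' thickness, pixel spacing, matrix size, convolution kernel, manufacturer;
#' MR additionally field strength and pulse-sequence fields; and so on) to
#' every readable instance in the index. Absent tags yield rows with `NA`
#' values (recorded absent, never defaulted).
#'
#' @param index a `qc_repo_index`.
#' @param ruleset a `qc_ruleset` (its `attributes` block is the spec).
#' @param cancer_by_patient optional named vector patient_id -> cancer type.
#' @return data.frame of class `qc_attributes`: one row per (instance,
#'   attribute) with `cancer_type`, `modality`, `provider`, `attribute`,
#'   `value` (character), `numeric_value` (`NA` for categoricals).
#' @export
extract_attributes <- function(index, ruleset = NULL, cancer_by_patient = NULL) {
  rs <- ruleset %||% load_ruleset()
  inst <- index$instances
  inst <- inst[inst$readable %in% TRUE, , drop = FALSE]
  rows <- list()
  if (nrow(inst) > 0) {
    spec <- rs$attributes
    ct_of <- function(pid) {
      if (is.null(cancer_by_patient)) return("unknown")
      v <- unname(cancer_by_patient[pid])
      ifelse(is.na(v), "unknown", v)
    }
    mods <- ifelse(is.na(inst$modality), "unknown", inst$modality)
    for (mod in unique(mods)) {
      attrs <- unlist(spec[[mod]] %||% spec$default %||%
                        c("slice_thickness", "pixel_spacing", "rows",
                          "columns", "manufacturer"))
      sub <- inst[mods == mod, , drop = FALSE]
      for (attr_name in attrs) {
        col <- unname(ATTRIBUTE_COLUMNS[attr_name])
        if (is.na(col) || !(col %in% names(sub))) next
        vals <- sub[[col]]
        rows[[length(rows) + 1L]] <- data.frame(
          cancer_type = ct_of(sub$patient_id), modality = mod,
          provider = sub$provider, patient_id = sub$patient_id,
          attribute = attr_name,
          value = as.character(vals),
          numeric_value = if (attr_name %in% NUMERIC_ATTRIBUTES)
            suppressWarnings(as.numeric(vals)) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- rbind_all(rows, c("cancer_type", "modality", "provider", "patient_id",
                           "attribute", "value", "numeric_value"))
  class(out) <- c("qc_attributes", "data.frame")
  out
}

#' Numeric profile: median with quartiles
#'
#' @param values numeric vector (NAs dropped).
#' @param method `"linear"` (interpolated order statistics, default) or
#'   `"nearest"` (nearest-rank).
#' @return list `median`, `q1`, `q3`, `n`; all `NA` when n = 0.
#' @export
numeric_profile <- function(values, method = c("linear", "nearest")) {
  method <- match.arg(method)
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0) return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_, n = 0L))
  type <- if (method == "linear") 7 else 3
  q <- unname(stats::quantile(v, probs = c(0.25, 0.5, 0.75), type = type))
  list(median = q[2], q1 = q[1], q3 = q[3], n = n)
}

#' Format a numeric profile as "median [q1 q3]"
#'
#' @param profile result of [numeric_profile()].
#' @param digits significant digits for each number.
#' @return character scalar like `"3 [2 3.75]"`.
#' @export
format_numeric_profile <- function(profile, digits = 3) {
  f <- function(x) format(signif(x, digits), trim = TRUE, scientific = FALSE)
  if (is.na(profile$median)) return("NA")
  sprintf("%s [%s %s]", f(profile$median), f(profile$q1), f(profile$q3))
}

#' Categorical profile: normalized shares
#'
#' Shares (half-up, 1 decimal) over non-missing values; categories whose
#' share falls below the floor collapse into `"Other"`.
#'
#' @param values character vector (NAs dropped).
#' @param other_floor minimum share to keep a category separate (default
#'   0.05).
#' @return data.frame `category`, `count`, `share_pct`, ordered by
#'   descending count with `"Other"` last; zero rows when n = 0.
#' @export
categorical_profile <- function(values, other_floor = 0.05) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0) {
    return(data.frame(category = character(), count = integer(),
                      share_pct = numeric(), stringsAsFactors = FALSE))
  }
  tab <- table(v)
  keep <- tab[tab / n >= other_floor]
  other <- sum(tab) - sum(keep)
  df <- data.frame(category = names(keep), count = as.integer(keep),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$category), , drop = FALSE]
  if (other > 0) {
    df <- rbind(df, data.frame(category = "Other", count = as.integer(other),
                               stringsAsFactors = FALSE))
  }
  df$share_pct <- vapply(df$count, function(k) pct_of(k, n, digits = 1), 0)
  rownames(df) <- NULL
  df
}

#' Profile all extracted attributes
#'
#' Aggregates an attribute table into per (cancer type, modality,
#' attribute) summaries: `"median [q1 q3]"` for numeric attributes and
#' share lists for categorical ones. Patient-level counts are included for
#' categorical attributes (number of patients as well as images per
#' category).
#'
#' @param attribute_table result of [extract_attributes()].
#' @param ruleset a `qc_ruleset` (supplies the category floor).
#' @return data.frame with `cancer_type`, `modality`, `attribute`, `kind`,
#'   `summary` (formatted), `n` (instances).
#' @export
profile_attributes <- function(attribute_table, ruleset = NULL) {
  rs <- ruleset %||% load_ruleset()
  floor_ <- rs$categorical_other_floor %||% 0.05
  at <- attribute_table
  rows <- list()
  if (nrow(at) > 0) {
    keys <- unique(at[c("cancer_type", "modality", "attribute")])
    for (i in seq_len(nrow(keys))) {
      sub <- at[at$cancer_type == keys$cancer_type[i] &
                  at$modality == keys$modality[i] &
                  at$attribute == keys$attribute[i], , drop = FALSE]
      numeric_kind <- keys$attribute[i] %in% NUMERIC_ATTRIBUTES
      if (numeric_kind) {
        pr <- numeric_profile(sub$numeric_value)
        s <- format_numeric_profile(pr)
        n <- pr$n
      } else {
        cp <- categorical_profile(sub$value, floor_)
        s <- paste(sprintf("%s: %.1f%%", cp$category, cp$share_pct),
                   collapse = " ")
        n <- sum(cp$count)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cancer_type = keys$cancer_type[i], modality = keys$modality[i],
        attribute = keys$attribute[i],
        kind = if (numeric_kind) "numeric" else "categorical",
        summary = s, n = n, stringsAsFactors = FALSE)
    }
  }
  rbind_all(rows, c("cancer_type", "modality", "attribute", "kind",
                    "summary", "n"))
}
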
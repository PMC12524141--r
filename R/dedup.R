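# Two-level duplicate / similarity detection.
#
# Level 1: rapid screening on the media-storage SOP instance UID, tag
# (0002,0003) - any UID shared by two or more files forms a candidate
# group. Cross-modality UID collisions are common de-identification
# artifacts, so such groups are annotated rather than treated as confirmed
# duplicates.
#
# Level 2: pairwise pixel MSE within a patient (intra) and across patients
# of a provider (inter). Images are resampled to a common grid (default
# 64x64, bilinear), min-max scaled to [0, 255] per image, and a slice pair
# is flagged when its MSE falls at or below the grade threshold
# (high = 0.1; normal is a config-exposed, more permissive value).
# All findings are advisory flags for curation; nothing is ever deleted.

#' Screen the repository for shared SOP instance UIDs
#'
#' @param index a `qc_repo_index` with headers loaded.
#' @return list of duplicate-candidate groups, each with `uid`, `members`
#'   (data.frame: file, provider, patient_id, timepoint, modality) and
#'   `cross_modality` (logical; likely de-identification artifact, not a
#'   confirmed duplicate).
#' @export
uid_screen <- function(index) {
  inst <- index$instances
  inst <- inst[!is.na(inst$uid), , drop = FALSE]
  if (nrow(inst) == 0) return(list())
  tab <- table(inst$uid)
  shared <- sort_c(names(tab[tab >= 2]))
  lapply(shared, function(u) {
    m <- inst[inst$uid == u,
              c("file", "provider", "patient_id", "timepoint", "modality"),
              drop = FALSE]
    rownames(m) <- NULL
    list(uid = u, members = m,
         cross_modality = length(unique(m$modality[!is.na(m$modality)])) > 1)
  })
}

# bilinear resampling of a matrix onto an n x n grid
resample_bilinear <- function(m, n = 64L) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr == n && nc == n) return(m)
  # sample positions mapped linearly onto the input grid
  if (nr == 1) { r0 <- rep(1L, n); fr <- rep(0, n) } else {
    ri <- seq(1, nr, length.out = n)
    r0 <- pmin(as.integer(floor(ri)), nr - 1L); fr <- ri - r0
  }
  if (nc == 1) { c0 <- rep(1L, n); fc <- rep(0, n) } else {
    ci <- seq(1, nc, length.out = n)
    c0 <- pmin(as.integer(floor(ci)), nc - 1L); fc <- ci - c0
  }
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  d <- m[r1, c0, drop = FALSE]; e <- m[r1, c1, drop = FALSE]
  wfr <- matrix(fr, n, n); wfc <- matrix(fc, n, n, byrow = TRUE)
  a * (1 - wfr) * (1 - wfc) + b * (1 - wfr) * wfc +
    d * wfr * (1 - wfc) + e * wfr * wfc
}

# min-max scale to [0, 255]; constant images become all-zeros
scale_255 <- function(m) {
  rng <- range(m)
  if (rng[2] == rng[1]) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Pixel mean squared error between two images
#'
#' Both images are resampled to a common square grid by bilinear
#' interpolation, min-max scaled to `[0, 255]` per image (a constant image
#' scales to all-zeros), and the MSE is the mean squared element-wise
#' difference. Symmetric in its arguments.
#'
#' @param image_a,image_b 2-D numeric intensity matrices (any sizes).
#' @param size common resampling grid size (default 64).
#' @return non-negative scalar MSE on the 0-255 intensity scale.
#' @export
pixel_mse <- function(image_a, image_b, size = 64L) {
  a <- scale_255(resample_bilinear(image_a, size))
  b <- scale_255(resample_bilinear(image_b, size))
  mean((a - b)^2)
}

# normalized slices of one series, cached per call tree
series_slices_norm <- function(series_path, size) {
  files <- sort_c(list.files(series_path, pattern = "\\.dcm$",
                             ignore.case = TRUE, full.names = TRUE))
  out <- list()
  for (f in files) {
    d <- tryCatch(dicom_read(f), error = function(e) NULL)
    px <- if (is.null(d)) NULL else dicom_pixels(d, rescale = TRUE)
    out[[length(out) + 1L]] <- if (is.null(px)) NULL else
      scale_255(resample_bilinear(px, size))
  }
  out
}

# Slice pairing: equal-length series compare index-aligned (one comparison
# per slice position, so an identical pair scores 100% and an n-slice pair
# yields n comparisons); unequal lengths compare all cross pairs while both
# stay under the cap, else align by index over the shorter series.
compare_series_pair <- function(slices_a, slices_b, threshold, cap) {
  na <- length(slices_a); nb <- length(slices_b)
  pairs <- if (na == nb || na > cap || nb > cap) {
    k <- seq_len(min(na, nb))
    data.frame(i = k, j = k)
  } else {
    expand.grid(i = seq_len(na), j = seq_len(nb))
  }
  n_comp <- 0L; n_flag <- 0L; n_skip <- 0L
  for (r in seq_len(nrow(pairs))) {
    a <- slices_a[[pairs$i[r]]]; b <- slices_b[[pairs$j[r]]]
    if (is.null(a) || is.null(b)) { n_skip <- n_skip + 1L; next }
    n_comp <- n_comp + 1L
    if (mean((a - b)^2) <= threshold) n_flag <- n_flag + 1L
  }
  list(comparisons = n_comp, flagged = n_flag, skipped = n_skip)
}

scan_pairs <- function(index, pair_df, grade, ruleset, scope) {
  rs <- ruleset %||% load_ruleset()
  threshold <- rs$dedup$thresholds[[grade]]
  if (is.null(threshold)) stopf("unknown similarity grade: %s", grade)
  size <- rs$dedup$resample_size
  cap <- rs$dedup$cross_pair_cap
  cache <- new.env(parent = emptyenv())
  get_slices <- function(p) {
    key <- p
    if (is.null(cache[[key]])) cache[[key]] <- series_slices_norm(p, size)
    cache[[key]]
  }
  rows <- list()
  for (r in seq_len(nrow(pair_df))) {
    pa <- pair_df$path_a[r]; pb <- pair_df$path_b[r]
    res <- compare_series_pair(get_slices(pa), get_slices(pb), threshold, cap)
    rows[[length(rows) + 1L]] <- data.frame(
      series_a = pa, series_b = pb,
      patient_a = pair_df$patient_a[r], patient_b = pair_df$patient_b[r],
      timepoint_a = pair_df$tp_a[r], timepoint_b = pair_df$tp_b[r],
      modality = pair_df$modality[r],
      comparisons = res$comparisons, flagged_slices = res$flagged,
      skipped_slices = res$skipped,
      similarity_pct = pct_of(res$flagged, res$comparisons),
      flagged = res$flagged > 0, stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows) == 0) {
    data.frame(series_a = character(), series_b = character(),
               patient_a = character(), patient_b = character(),
               timepoint_a = integer(), timepoint_b = integer(),
               modality = character(), comparisons = integer(),
               flagged_slices = integer(), skipped_slices = integer(),
               similarity_pct = numeric(), flagged = logical(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  structure(list(scope = scope, grade = grade, threshold = threshold,
                 pairs = pairs,
                 n_comparisons = nrow(pairs),
                 n_flagged = sum(pairs$flagged)),
            class = "qc_similarity")
}

series_pair_df <- function(ser, across_patients) {
  rows <- list()
  for (mod in sort_c(unique(ser$modality[!is.na(ser$modality)]))) {
    sm <- ser[!is.na(ser$modality) & ser$modality == mod, , drop = FALSE]
    n <- nrow(sm)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      if (across_patients && sm$patient_id[i] == sm$patient_id[j]) next
      if (!across_patients && sm$patient_id[i] != sm$patient_id[j]) next
      rows[[length(rows) + 1L]] <- data.frame(
        path_a = sm$path[i], path_b = sm$path[j],
        patient_a = sm$patient_id[i], patient_b = sm$patient_id[j],
        tp_a = sm$timepoint[i], tp_b = sm$timepoint[j],
        modality = mod, stringsAsFactors = FALSE)
    }
  }
  rbind_all(rows, c("path_a", "path_b", "patient_a", "patient_b",
                    "tp_a", "tp_b", "modality"))
}

#' Intra-patient similarity scan
#'
#' Compares all unordered same-modality series pairs within one patient's
#' folder, slice-wise. A series pair is flagged when at least one slice
#' pair has MSE at or below the grade threshold. Unreadable pixel data is
#' skipped and counted as non-assessed.
#'
#' @param index a `qc_repo_index`.
#' @param provider provider id.
#' @param patient_id patient id.
#' @param grade `"high"` (threshold 0.1) or `"normal"` (permissive).
#' @param ruleset a `qc_ruleset`.
#' @return object of class `qc_similarity` with per-pair results.
#' @export
intra_patient_scan <- function(index, provider, patient_id, grade = "high",
                               ruleset = NULL) {
  ser <- index$series[index$series$provider == provider &
                        index$series$patient_id == patient_id, , drop = FALSE]
  scan_pairs(index, series_pair_df(ser, across_patients = FALSE),
             grade, ruleset, scope = "intra")
}

#' Inter-patient similarity scan
#'
#' As [intra_patient_scan()], but pairs are drawn across different patients
#' of one provider (same modality only; cross-modality UID collisions are
#' handled by [uid_screen()]).
#'
#' @inheritParams intra_patient_scan
#' @return object of class `qc_similarity`.
#' @export
inter_patient_scan <- function(index, provider, grade = "high", ruleset = NULL) {
  ser <- index$series[index$series$provider == provider, , drop = FALSE]
  scan_pairs(index, series_pair_df(ser, across_patients = TRUE),
             grade, ruleset, scope = "inter")
}

#' Scan every patient of every provider (intra scope)
#'
#' Convenience wrapper running [intra_patient_scan()] over the whole index
#' and concatenating the findings.
#'
#' @inheritParams intra_patient_scan
#' @return object of class `qc_similarity`.
#' @export
intra_scan_all <- function(index, grade = "high", ruleset = NULL) {
  pats <- index$patients
  res <- lapply(seq_len(nrow(pats)), function(i)
    intra_patient_scan(index, pats$provider[i], pats$patient_id[i],
                       grade, ruleset))
  pairs <- do.call(rbind, lapply(res, `[[`, "pairs"))
  structure(list(scope = "intra", grade = grade,
                 threshold = if (length(res) > 0) res[[1]]$threshold else NA,
                 pairs = pairs %||% data.frame(),
                 n_comparisons = if (is.null(pairs)) 0L else nrow(pairs),
                 n_flagged = if (is.null(pairs)) 0L else sum(pairs$flagged)),
            class = "qc_similarity")
}

#' Similarity percentage of a series pair
#'
#' The ratio of flagged slice-pair comparisons to the total slice-pair
#' comparisons performed, as a percentage (half-up, 2 decimals).
#'
#' @param flagged number of flagged slice pairs.
#' @param comparisons total slice-pair comparisons (> 0).
#' @return percentage in `[0, 100]`; `NA` when `comparisons` is 0.
#' @export
similarity_percentage <- function(flagged, comparisons) {
  pct_of(flagged, comparisons)
}

#' Stratify similarity findings by timepoint gap
#'
#' @param findings a `qc_similarity`.
#' @return data.frame with columns `gap` (|tA - tB|, or `"unknown"`),
#'   `comparisons` (series pairs) and `flagged`.
#' @export
stratify_by_timepoint_gap <- function(findings) {
  p <- findings$pairs
  if (is.null(p) || nrow(p) == 0) {
    return(data.frame(gap = character(), comparisons = integer(),
                      flagged = integer(), stringsAsFactors = FALSE))
  }
  gap <- abs(p$timepoint_a - p$timepoint_b)
  gap_chr <- ifelse(is.na(gap), "unknown", as.character(gap))
  agg <- stats::aggregate(cbind(comparisons = rep(1L, nrow(p)),
                                flagged = as.integer(p$flagged)),
                          by = list(gap = gap_chr), FUN = sum)
  agg[order(agg$gap), , drop = FALSE]
}

#' Summarize similarity findings by modality
#'
#' Shape of the intra-directory result table: comparisons performed and
#' pairs with at least one flag, grouped by modality.
#'
#' @param findings a `qc_similarity`.
#' @return data.frame with `modality`, `comparisons`, `flagged`.
#' @export
summarize_by_modality <- function(findings) {
  p <- findings$pairs
  if (is.null(p) || nrow(p) == 0) {
    return(data.frame(modality = character(), comparisons = integer(),
                      flagged = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(cbind(comparisons = rep(1L, nrow(p)),
                                flagged = as.integer(p$flagged)),
                          by = list(modality = p$modality), FUN = sum)
  agg[order(agg$modality), , drop = FALSE]
}

#' @export
print.qc_similarity <- function(x, ...) {
  cat(sprintf("<qc_similarity> scope %s, grade %s (MSE <= %s): %d/%d series pairs flagged\n",
              x$scope, x$grade, format(x$threshold), x$n_flagged, x$n_comparisons))
  invisible(x)
}
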
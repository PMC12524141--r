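# Synthetic repository generation with controlled defect injection.
#
# The generator emulates the full repository layout (DICOM series, NIfTI
# masks, clinical CSVs) and injects every defect class the quality checks
# look for, at configured rates, into disjoint records. Its ground-truth
# manifest carries the injected-defect ledger plus the closed-form expected
# value of every count-based metric, making parameter recovery exactly
# testable: with one defect class per dimension at rate p, each dimension
# equals 100*(1-p).
#
# Baseline conditions (defaults): 3 providers, 20 patients each, the four
# cancer types mixed per provider, two timepoints per patient (diagnosis +
# one follow-up) with one series of the cancer's primary modality at each,
# two slices per series, 32x32 procedural phantom images (smooth ellipse
# gradient plus acquisition noise), one annotation mask per series.

CANCER_MODALITY <- c(breast = "MG", lung = "CT", colorectal = "CT", prostate = "MR")
CANCER_HISTOLOGY <- c(breast = "IDC", lung = "Adenocarcinoma",
                      colorectal = "Adenocarcinoma", prostate = "Adenocarcinoma")

DEFECT_CLASSES <- c("missing_mandatory", "invalid_value", "crosslink_break",
                    "modality_mismatch", "naming_violation",
                    "duplicate_series_intra", "duplicate_series_inter",
                    "mask_roi_mismatch", "mask_slice_mismatch", "empty_mask",
                    "unknown_label", "retained_sex_tag", "retained_age_tag",
                    "date_hash_wrong_id", "burnt_in_report")

#' Generation parameters for the synthetic repository
#'
#' All defect rates live in `[0, 1]` and default to 0; the seed fully
#' determines the output tree (same seed, byte-identical repository).
#'
#' @param seed RNG seed.
#' @param providers number of data providers (`DP1`, `DP2`, ...).
#' @param patients_per_provider patients per provider.
#' @param cancer_mix named proportions over cancer types (largest-remainder
#'   rounding makes per-provider counts exact).
#' @param timepoints timepoints per patient (1 = diagnosis).
#' @param slices_per_series DICOM instances per series.
#' @param image_size in-plane image size in pixels.
#' @param rates named list of defect rates (see `DEFECT_CLASSES` in the
#'   package sources); unnamed classes default to 0.
#' @param sex_proportions per cancer type, named proportions over M/F.
#' @param grade_proportions named proportions over grades "1"-"3".
#' @param include_masks write annotation masks alongside series.
#' @param compress_masks write `.nii.gz` (TRUE) or plain `.nii`.
#' @return list of class `qc_sim_params`.
#' @export
qc_sim_params <- function(seed = 1L,
                          providers = 3L,
                          patients_per_provider = 20L,
                          cancer_mix = c(breast = 0.30, lung = 0.30,
                                         colorectal = 0.25, prostate = 0.15),
                          timepoints = 2L,
                          slices_per_series = 2L,
                          image_size = 32L,
                          rates = list(),
                          sex_proportions = list(
                            breast = c(F = 0.95, M = 0.05),
                            lung = c(M = 0.65, F = 0.35),
                            colorectal = c(M = 0.55, F = 0.45),
                            prostate = c(M = 1)),
                          grade_proportions = c(`1` = 0.3, `2` = 0.5, `3` = 0.2),
                          include_masks = TRUE,
                          compress_masks = TRUE) {
  full_rates <- setNames(as.list(rep(0, length(DEFECT_CLASSES))), DEFECT_CLASSES)
  for (nm in names(rates)) {
    if (!nm %in% DEFECT_CLASSES) stopf("unknown defect class: %s", nm)
    r <- rates[[nm]]
    if (r < 0 || r > 1) stopf("rate %s out of [0,1]: %s", nm, r)
    full_rates[[nm]] <- r
  }
  structure(list(seed = as.integer(seed), providers = as.integer(providers),
                 patients_per_provider = as.integer(patients_per_provider),
                 cancer_mix = cancer_mix / sum(cancer_mix),
                 timepoints = as.integer(timepoints),
                 slices_per_series = as.integer(slices_per_series),
                 image_size = as.integer(image_size),
                 rates = full_rates,
                 sex_proportions = sex_proportions,
                 grade_proportions = grade_proportions / sum(grade_proportions),
                 include_masks = isTRUE(include_masks),
                 compress_masks = isTRUE(compress_masks)),
            class = "qc_sim_params")
}

# integral class counts from proportions by largest remainder
counts_from_props <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(props))
}

phantom_image <- function(size) {
  cx <- stats::runif(1, 0.40, 0.60) * size
  cy <- stats::runif(1, 0.40, 0.60) * size
  rx <- stats::runif(1, 0.25, 0.38) * size
  ry <- stats::runif(1, 0.25, 0.38) * size
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  base <- matrix(0, size, size)
  base[inside] <- 80 + 150 * (xs[inside] / size)
  noise <- matrix(sample(0:40, size * size, replace = TRUE), size, size)
  pmin(round(base + noise), 255)
}

report_image <- function(size) {
  img <- matrix(255L, size, size)
  for (r in seq(4, size - 4, by = 4)) {
    len <- sample(seq(floor(size * 0.3), floor(size * 0.8)), 1)
    start <- sample(seq(2, size - len), 1)
    img[r, start:(start + len - 1)] <- 0L
  }
  img
}

# duplicate a series byte-for-byte except for patient id / visit date,
# preserving UIDs and pixel content
copy_series_restamped <- function(src, dst, patient_id, study_date) {
  dir.create(dst, recursive = TRUE, showWarnings = FALSE)
  meta_only <- c("FileMetaInformationVersion", "TransferSyntaxUID",
                 "ImplementationClassUID", "MediaStorageSOPClassUID",
                 "Rows", "Columns", "SamplesPerPixel",
                 "PhotometricInterpretation", "BitsAllocated", "BitsStored",
                 "HighBit", "PixelRepresentation")
  for (f in sort_c(list.files(src, full.names = TRUE))) {
    d <- dicom_read(f)
    a <- d$attributes[setdiff(names(d$attributes), meta_only)]
    a$PatientID <- patient_id
    a$StudyDate <- study_date
    dicom_write(file.path(dst, basename(f)), a,
                pixels = dicom_pixels(d, rescale = FALSE))
  }
  invisible(dst)
}

blob_mask <- function(size, slices, label) {
  arr <- array(0L, dim = c(size, size, slices))
  a <- floor(size * 0.35); b <- floor(size * 0.6)
  arr[a:b, a:b, ] <- as.integer(label)
  arr
}

#' Generate a synthetic repository with a ground-truth manifest
#'
#' Writes a complete repository tree under `root` and returns the manifest
#' ledger of every injected defect plus closed-form expected metric values.
#' Defects of different classes land on disjoint records; rates whose
#' required record counts exceed what the composition provides raise an
#' error.
#'
#' @param params a [qc_sim_params()].
#' @param root output directory (created; must not already contain a
#'   repository).
#' @return list of class `qc_manifest` (fields `root`, `params`, `counts`,
#'   `defects`, `expected`).
#' @export
generate_repository <- function(params = qc_sim_params(), root = tempfile("qcrepo")) {
  p <- params
  if (!inherits(p, "qc_sim_params")) stopf("params must come from qc_sim_params()")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(p$seed)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)

  provs <- sprintf("DP%d", seq_len(p$providers))
  npat <- p$providers * p$patients_per_provider

  # ---- patient composition (deterministic, largest-remainder exact) ----
  pats <- list()
  pid_counter <- 0L
  for (pr in provs) {
    mix <- counts_from_props(p$patients_per_provider, p$cancer_mix)
    cancers <- rep(names(mix), mix)
    for (ct in cancers) {
      pid_counter <- pid_counter + 1L
      pats[[pid_counter]] <- data.frame(
        provider = pr, patient_id = sprintf("P%04d", pid_counter),
        cancer_type = ct, stringsAsFactors = FALSE)
    }
  }
  pats <- do.call(rbind, pats)
  pats$idx <- seq_len(npat)
  # demographics per (provider, cancer) group, exact proportions
  pats$sex <- NA_character_; pats$grade <- NA_character_
  for (pr in provs) for (ct in unique(pats$cancer_type)) {
    idx <- which(pats$provider == pr & pats$cancer_type == ct)
    if (length(idx) == 0) next
    sx <- counts_from_props(length(idx), p$sex_proportions[[ct]])
    pats$sex[idx] <- rep(names(sx), sx)
    gr <- counts_from_props(length(idx), p$grade_proportions)
    pats$grade[idx] <- rep(names(gr), gr)
  }
  pats$age <- as.character(40L + ((seq_len(npat) - 1L) * 7L) %% 41L)
  pats$stage <- c("I", "II", "III", "IV")[((seq_len(npat) - 1L) %% 4L) + 1L]
  pats$histological_type <- unname(CANCER_HISTOLOGY[pats$cancer_type])
  pats$biopsy <- "Biopsy"
  pats$er_status <- "Positive"
  pats$pr_status <- "Negative"
  pats$study_phase <- "retrospective"
  pats$modality <- unname(CANCER_MODALITY[pats$cancer_type])

  # ---- defect assignment ----
  # Two disjoint patient pools, one per interaction group: clinical-table
  # classes (they touch different template fields and cannot perturb each
  # other's dimension) and imaging/file classes (they touch the same
  # directories, declarations and headers, so they must not share a
  # patient). Classes across pools are free to coincide - their record
  # universes are distinct - which is what keeps every closed-form
  # expectation exact even at high rates.
  new_pool <- function() {
    pool <- sample(seq_len(npat))
    cursor <- 0L
    function(k, class) {
      if (cursor + k > npat)
        stopf("impossible composition: defect rates exceed patient count at %s", class)
      out <- pool[seq_len(k) + cursor]
      cursor <<- cursor + k
      sort(out)
    }
  }
  take_clinical <- new_pool()
  take_imaging <- new_pool()
  r <- p$rates
  k_miss <- round(r$missing_mandatory * npat)
  k_cross <- round(r$crosslink_break * npat)
  k_modmis <- round(r$modality_mismatch * npat)
  k_naming <- round(r$naming_violation * npat)
  k_dup_intra <- round(r$duplicate_series_intra * npat)
  k_dup_inter_pairs <- floor(round(r$duplicate_series_inter * npat) / 2)
  k_sex <- round(r$retained_sex_tag * npat)
  k_age <- round(r$retained_age_tag * npat)
  k_wrongid <- round(r$date_hash_wrong_id * npat)
  k_burnt <- round(r$burnt_in_report * npat)

  defects <- list()
  defects$missing_mandatory <- take_clinical(k_miss, "missing_mandatory")
  defects$crosslink_break <- take_clinical(k_cross, "crosslink_break")
  defects$modality_mismatch <- take_imaging(k_modmis, "modality_mismatch")
  defects$naming_violation <- take_imaging(k_naming, "naming_violation")
  defects$duplicate_series_intra <- take_imaging(k_dup_intra, "duplicate_series_intra")
  inter_flat <- take_imaging(2 * k_dup_inter_pairs, "duplicate_series_inter")
  # pair members within a provider where possible: pool order is random, so
  # simply pair consecutive picks from the same provider-sorted list
  inter_flat <- inter_flat[order(pats$provider[inter_flat])]
  defects$duplicate_series_inter <- if (k_dup_inter_pairs > 0)
    matrix(inter_flat, ncol = 2, byrow = TRUE) else matrix(integer(0), ncol = 2)
  defects$retained_sex_tag <- take_imaging(k_sex, "retained_sex_tag")
  defects$retained_age_tag <- take_imaging(k_age, "retained_age_tag")
  defects$date_hash_wrong_id <- take_imaging(k_wrongid, "date_hash_wrong_id")
  defects$burnt_in_report <- take_imaging(k_burnt, "burnt_in_report")

  # clinical table defects
  miss_fields <- c("stage", "histological_type")  # 2 mandatory fields blanked
  for (i in defects$missing_mandatory) pats[i, miss_fields] <- NA_character_
  for (i in defects$crosslink_break) pats$biopsy[i] <- "No Biopsy"

  # invalid values: slots are (patient, field) pairs over rule-covered
  # fields, avoiding fields blanked by completeness defects and the
  # cross-link trio in cross-link patients
  invalidable <- c(sex = "Female", age = "200", grade = "9", stage = "3",
                   biopsy = "Maybe", er_status = "Pos", pr_status = "Neg",
                   study_phase = "phase2")
  n_values <- npat * 10L - 2L * k_miss  # 10 rule-covered values per patient
  k_inv <- round(r$invalid_value * n_values)
  slots <- list()
  for (i in seq_len(npat)) {
    flds <- names(invalidable)
    if (i %in% defects$missing_mandatory) flds <- setdiff(flds, miss_fields)
    if (i %in% defects$crosslink_break)
      flds <- setdiff(flds, c("biopsy", "er_status", "pr_status"))
    for (f in flds) slots[[length(slots) + 1L]] <- c(i, f)
  }
  if (k_inv > length(slots))
    stopf("impossible composition: invalid_value rate needs %d slots, have %d",
          k_inv, length(slots))
  sel <- if (k_inv > 0) sample(length(slots))[seq_len(k_inv)] else integer(0)
  inv_records <- character(0)
  for (s in sel) {
    i <- as.integer(slots[[s]][1]); f <- slots[[s]][2]
    pats[i, f] <- unname(invalidable[f])
    inv_records <- c(inv_records, paste0(pats$patient_id[i], ":", f))
  }
  defects$invalid_value <- sort(inv_records)

  # ---- write imaging data ----
  tps <- seq_len(p$timepoints)
  size <- p$image_size
  base_date <- as.Date("2020-01-06")
  series_paths <- list()
  file_count_by_patient <- integer(npat)
  mask_info <- list()
  wrong_id_of <- function(i) {
    same <- which(pats$provider == pats$provider[i])
    alt <- setdiff(same, i)
    pats$patient_id[if (length(alt) > 0) alt[1] else ((i %% npat) + 1L)]
  }

  for (i in seq_len(npat)) {
    pr <- pats$provider[i]; pid <- pats$patient_id[i]
    mod <- pats$modality[i]
    off <- date_offset_days(pid)
    naming <- i %in% defects$naming_violation
    for (tp in tps) {
      moddir <- if (naming) tolower(mod) else mod
      sdir <- file.path(root, pr, pid, sprintf("T%d", tp), moddir, "S1")
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      sdate <- shift_dicom_date(format(base_date + (tp - 1) * 42, "%Y%m%d"), off)
      for (sl in seq_len(p$slices_per_series)) {
        uid <- sprintf("1.2.826.0.1.%d.%d.%d.1.%d", p$seed, i, tp, sl)
        burnt <- (i %in% defects$burnt_in_report) && tp == 1L && sl == 1L
        px <- if (burnt) report_image(size) else phantom_image(size)
        attrs <- list(
          Modality = mod,
          MediaStorageSOPInstanceUID = uid,
          SOPClassUID = if (burnt) SOP_CLASS_SECONDARY_CAPTURE else
            if (mod == "MR") SOP_CLASS_MR else SOP_CLASS_CT,
          StudyDate = sdate,
          PatientID = if (i %in% defects$date_hash_wrong_id) wrong_id_of(i) else pid,
          Manufacturer = c("GE MEDICAL SYSTEMS", "SIEMENS", "Philips")[(i %% 3L) + 1L],
          SliceThickness = c(1.5, 2, 3, 5)[(i %% 4L) + 1L],
          PixelSpacing = c(0.98, 0.98))
        if (mod == "CT") attrs$ConvolutionKernel <- c("STANDARD", "LUNG")[(i %% 2L) + 1L]
        if (mod == "MR") {
          attrs$MagneticFieldStrength <- c(1.5, 3)[(i %% 2L) + 1L]
          attrs$ScanningSequence <- "SE"
        }
        if (i %in% defects$retained_sex_tag) attrs$PatientSex <- pats$sex[i]
        if (i %in% defects$retained_age_tag)
          attrs$PatientAge <- sprintf("%03dY", as.integer(pats$age[i]))
        dicom_write(file.path(sdir, sprintf("I%03d.dcm", sl)), attrs, pixels = px)
        file_count_by_patient[i] <- file_count_by_patient[i] + 1L
      }
      series_paths[[paste(i, tp, sep = ":")]] <- sdir
    }
  }

  # intra-patient duplicate series: copy T1/S1 as T1/S2, declaration updated
  for (i in defects$duplicate_series_intra) {
    src <- series_paths[[paste(i, 1L, sep = ":")]]
    dst <- file.path(dirname(src), "S2")
    dir.create(dst, showWarnings = FALSE)
    file.copy(list.files(src, full.names = TRUE), dst)
    file_count_by_patient[i] <- file_count_by_patient[i] + p$slices_per_series
  }
  # inter-patient duplicates: the target's T1/S2 holds the source's pixel
  # data and UIDs; patient id and visit date are re-stamped to the target
  # (the duplicate is the image content + UID, not a de-id defect)
  if (nrow(defects$duplicate_series_inter) > 0) {
    for (k in seq_len(nrow(defects$duplicate_series_inter))) {
      a <- defects$duplicate_series_inter[k, 1]
      b <- defects$duplicate_series_inter[k, 2]
      src <- series_paths[[paste(a, 1L, sep = ":")]]
      dst <- file.path(root, pats$provider[b], pats$patient_id[b], "T1",
                       pats$modality[a], "S2")
      b_date <- shift_dicom_date(format(base_date, "%Y%m%d"),
                                 date_offset_days(pats$patient_id[b]))
      copy_series_restamped(src, dst, pats$patient_id[b], b_date)
      file_count_by_patient[b] <- file_count_by_patient[b] + p$slices_per_series
    }
  }

  # ---- annotation masks (with mask-level defects, disjoint by mask) ----
  n_masks <- 0L
  if (p$include_masks) {
    mask_list <- list()
    for (i in seq_len(npat)) for (tp in tps) {
      mask_list[[length(mask_list) + 1L]] <- c(i, tp)
    }
    n_masks <- length(mask_list)
    mpool <- sample(n_masks)
    mcur <- 0L
    take_masks <- function(k, class) {
      if (mcur + k > n_masks)
        stopf("impossible composition: mask defect rates exceed mask count at %s", class)
      out <- mpool[seq_len(k) + mcur]
      mcur <<- mcur + k
      sort(out)
    }
    m_roi <- take_masks(round(r$mask_roi_mismatch * n_masks), "mask_roi_mismatch")
    m_slice <- take_masks(round(r$mask_slice_mismatch * n_masks), "mask_slice_mismatch")
    m_empty <- take_masks(round(r$empty_mask * n_masks), "empty_mask")
    m_unk <- take_masks(round(r$unknown_label * n_masks), "unknown_label")
    ext <- if (p$compress_masks) ".nii.gz" else ".nii"
    for (k in seq_len(n_masks)) {
      i <- mask_list[[k]][1]; tp <- mask_list[[k]][2]
      sdir <- series_paths[[paste(i, tp, sep = ":")]]
      mdims <- c(size, size)
      slices <- p$slices_per_series
      if (k %in% m_roi) mdims <- mdims %/% 2L
      if (k %in% m_slice) slices <- slices + 2L
      label <- if (k %in% m_unk) 9L else c(3L, 1L)[(k %% 5L == 0L) + 1L]
      arr <- if (k %in% m_empty) array(0L, dim = c(mdims, slices)) else
        blob_mask(mdims[1], slices, label)[seq_len(mdims[1]),
                                           seq_len(mdims[2]), , drop = FALSE]
      mpath <- file.path(dirname(sdir), paste0("S1_annotation", ext))
      RNifti::writeNifti(arr, mpath)
      mask_info[[k]] <- data.frame(
        patient = pats$patient_id[i], timepoint = tp, path = mpath,
        roi_mismatch = k %in% m_roi, slice_mismatch = k %in% m_slice,
        empty = k %in% m_empty, unknown_label = k %in% m_unk,
        label = if (k %in% m_empty) NA_integer_ else label,
        stringsAsFactors = FALSE)
    }
    defects$mask_roi_mismatch <- m_roi
    defects$mask_slice_mismatch <- m_slice
    defects$empty_mask <- m_empty
    defects$unknown_label <- m_unk
  }

  # ---- clinical CSVs (one per cancer type) ----
  decl <- function(i, tp) {
    mod <- pats$modality[i]
    n_series <- 1L + (tp == 1L) * ((i %in% defects$duplicate_series_intra) +
                                     (i %in% defects$duplicate_series_inter[, 2]))
    if (i %in% defects$modality_mismatch && tp == 1L) {
      # declared modality differs from the provided one
      wrong <- if (pats$modality[i] == "MG") "CT" else "MG"
      return(wrong)
    }
    paste(rep(mod, n_series), collapse = ";")
  }
  # inter-duplicate targets host a series of the *source's* modality
  inter_extra <- character(0)
  clin_cols <- c("patient_id", "provider", "cancer_type", "study_phase", "sex",
                 "age", "grade", "stage", "histological_type", "biopsy",
                 "er_status", "pr_status")
  for (ct in unique(pats$cancer_type)) {
    sub <- pats[pats$cancer_type == ct, , drop = FALSE]
    tbl <- sub[clin_cols]
    for (tp in tps) {
      tbl[[sprintf("modalities_t%d", tp)]] <- vapply(sub$idx, decl, "", tp = tp)
    }
    # inter-duplicate targets: add the copied modality to the declaration if
    # it differs from their own (keeps integrity clean for these patients)
    if (nrow(defects$duplicate_series_inter) > 0) {
      for (k in seq_len(nrow(defects$duplicate_series_inter))) {
        a <- defects$duplicate_series_inter[k, 1]
        b <- defects$duplicate_series_inter[k, 2]
        if (pats$cancer_type[b] == ct && pats$modality[a] != pats$modality[b]) {
          j <- which(tbl$patient_id == pats$patient_id[b])
          tbl$modalities_t1[j] <- paste(c(pats$modality[b], pats$modality[a]),
                                        collapse = ";")
        }
      }
    }
    utils::write.csv(tbl, file.path(root, sprintf("clinical_%s.csv", ct)),
                     row.names = FALSE, na = "")
  }

  # ---- closed-form expected metrics ----
  total_files <- sum(file_count_by_patient)
  viol_files <- sum(file_count_by_patient[sort(unique(c(
    defects$retained_sex_tag, defects$retained_age_tag,
    defects$date_hash_wrong_id)))]) + k_burnt
  integrity_den <- npat * p$timepoints + k_modmis
  integrity_fail <- 2L * k_modmis + p$timepoints * k_naming
  mask_df <- rbind_all(mask_info, NULL)
  expected <- list(
    completeness = if (p$timepoints >= 2)
      round_half_up(100 * (1 - k_miss / npat)) else 0,
    validity = if (n_values > 0) round_half_up(100 * (1 - k_inv / n_values)) else NA,
    consistency = round_half_up(100 * (1 - k_cross / npat)),
    integrity = round_half_up(100 * (1 - integrity_fail / integrity_den)),
    anonymization = round_half_up(100 * (1 - viol_files / total_files)),
    annotation_consistency = if (n_masks > 0)
      round_half_up(100 * (1 - (length(defects$mask_roi_mismatch) +
                                  length(defects$mask_slice_mismatch)) / n_masks))
      else NA,
    empty_mask_pct = if (n_masks > 0)
      round_half_up(100 * length(defects$empty_mask) / n_masks, 1) else NA,
    intra_duplicate_pairs = k_dup_intra,
    inter_duplicate_pairs = k_dup_inter_pairs)

  structure(list(
    root = root,
    params = p,
    patients = pats,
    counts = list(providers = p$providers, patients = npat,
                  series = length(series_paths) + k_dup_intra + k_dup_inter_pairs,
                  files = total_files, masks = n_masks,
                  rule_covered_values = n_values),
    defects = defects,
    masks = mask_df,
    expected = expected), class = "qc_manifest")
}

#' @export
print.qc_manifest <- function(x, ...) {
  cat(sprintf("<qc_manifest> %s\n  %d providers, %d patients, %d series, %d files, %d masks\n",
              x$root, x$counts$providers, x$counts$patients, x$counts$series,
              x$counts$files, x$counts$masks))
  inj <- vapply(x$defects, function(d) if (is.matrix(d)) nrow(d) else length(d), 0L)
  inj <- inj[inj > 0]
  if (length(inj) > 0) {
    cat("  injected defects:\n")
    for (nm in names(inj)) cat(sprintf("    %-24s %d\n", nm, inj[[nm]]))
  }
  cat("  expected metrics:",
      paste(sprintf("%s=%s", names(x$expected), unlist(x$expected)),
            collapse = " "), "\n")
  invisible(x)
}

#' Write a manifest to JSON
#'
#' @param manifest a `qc_manifest`.
#' @param path output path (default `<root>/manifest.json`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path = file.path(manifest$root, "manifest.json")) {
  m <- manifest
  out <- list(
    root = m$root,
    seed = m$params$seed,
    counts = m$counts,
    defects = lapply(m$defects, function(d)
      if (is.matrix(d)) apply(d, 1, identity, simplify = FALSE) else d),
    expected = m$expected)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
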
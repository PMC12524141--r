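rs <- load_ruleset()

# independent oracle: elementwise double loop over explicitly scaled images
mse_loop <- function(a, b) {
  scale01 <- function(m) {
    r <- range(m)
    if (r[1] == r[2]) return(m * 0)
    (m - r[1]) / (r[2] - r[1]) * 255
  }
  a <- scale01(a); b <- scale01(b)
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  s / (nrow(a) * ncol(a))
}

test_that("pixel MSE matches the brute-force oracle and is symmetric", {
  a <- noise_image(64, 1); b <- noise_image(64, 2)
  expect_equal(pixel_mse(a, a), 0)
  expect_equal(pixel_mse(a, b), mse_loop(a, b))
  expect_equal(pixel_mse(a, b), pixel_mse(b, a))
  # inverted image: expected value from the direct double loop
  inv <- 255 - a
  expect_equal(pixel_mse(a, inv), mse_loop(a, inv))
  # constant image scales to all-zeros
  cst <- matrix(7, 64, 64)
  expect_equal(pixel_mse(cst, matrix(0, 64, 64)), 0)
})

test_that("pixel MSE resamples unequal sizes onto a common grid", {
  a <- noise_image(32, 3)
  b <- noise_image(48, 4)
  m <- pixel_mse(a, b)
  expect_gte(m, 0)
  # a smooth image compared with its own upsampling is near-identical
  sm <- outer(1:16, 1:16, function(i, j) i + j)
  up <- cimqc:::resample_bilinear(sm, 64L)
  expect_lt(pixel_mse(sm, up), 0.1)
})

test_that("UID screening finds shared UIDs and annotates cross-modality groups", {
  d <- withr::local_tempdir()
  mk <- function(pat, mod, uid, slice = "I001.dcm") {
    sd <- file.path(d, "DP1", pat, "T1", mod, "S1")
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    dicom_write(file.path(sd, slice),
                list(Modality = mod, MediaStorageSOPInstanceUID = uid),
                pixels = noise_image(8, nchar(uid)))
  }
  mk("P001", "CT", "1.1.1"); mk("P002", "CT", "1.1.2")
  idx <- scan_repository(d)
  expect_length(uid_screen(idx), 0)        # all unique
  mk("P003", "CT", "1.1.1")                # same UID in a second patient
  mk("P004", "PT", "1.1.2")                # CT/PT collision
  idx2 <- scan_repository(d)
  groups <- uid_screen(idx2)
  expect_length(groups, 2)
  cross <- vapply(groups, `[[`, TRUE, "cross_modality")
  expect_equal(sum(cross), 1)
  expect_equal(nrow(groups[[which(!cross)]]$members), 2)
})

test_that("intra scan flags byte-identical series and skips singletons", {
  man <- local_repo(qc_sim_params(seed = 31, providers = 1,
                                  patients_per_provider = 5, timepoints = 1,
                                  include_masks = FALSE,
                                  rates = list(duplicate_series_intra = 0.2)))
  idx <- scan_repository(man$root)
  dup_pat <- man$patients$patient_id[man$defects$duplicate_series_intra]
  f <- intra_patient_scan(idx, "DP1", dup_pat, grade = "high", ruleset = rs)
  expect_equal(f$n_flagged, 1)
  expect_equal(f$pairs$similarity_pct[f$pairs$flagged], 100)
  clean_pat <- setdiff(man$patients$patient_id, dup_pat)[1]
  f0 <- intra_patient_scan(idx, "DP1", clean_pat, grade = "high", ruleset = rs)
  expect_equal(f0$n_comparisons, 0)   # one series, nothing to compare
})

test_that("exactly the planted duplicate is flagged among all intra pairs", {
  man <- local_repo(qc_sim_params(seed = 32, providers = 1,
                                  patients_per_provider = 5,
                                  include_masks = FALSE,
                                  rates = list(duplicate_series_intra = 0.2)))
  idx <- scan_repository(man$root)
  f <- intra_scan_all(idx, grade = "high", ruleset = rs)
  expect_equal(f$n_flagged, 1)
  # oracle: brute-force all same-patient same-modality pairs
  ser <- idx$series
  n_bf <- 0L
  for (i in seq_len(nrow(ser) - 1)) for (j in seq(i + 1, nrow(ser))) {
    if (ser$patient_id[i] != ser$patient_id[j]) next
    if (ser$modality[i] != ser$modality[j]) next
    s1 <- cimqc:::series_slices_norm(ser$path[i], 64L)
    s2 <- cimqc:::series_slices_norm(ser$path[j], 64L)
    hit <- FALSE
    for (a in s1) for (b in s2) if (mean((a - b)^2) <= 0.1) hit <- TRUE
    n_bf <- n_bf + hit
  }
  expect_equal(f$n_flagged, n_bf)
})

test_that("inter scan flags series planted across patients", {
  man <- local_repo(qc_sim_params(seed = 33, providers = 1,
                                  patients_per_provider = 6, timepoints = 1,
                                  cancer_mix = c(lung = 1),
                                  include_masks = FALSE,
                                  rates = list(duplicate_series_inter = 1 / 3)))
  idx <- scan_repository(man$root)
  f <- inter_patient_scan(idx, "DP1", grade = "high", ruleset = rs)
  expect_equal(f$n_flagged, nrow(man$defects$duplicate_series_inter))
  # a single-patient provider yields zero comparisons
  man2 <- local_repo(qc_sim_params(seed = 34, providers = 1,
                                   patients_per_provider = 1,
                                   include_masks = FALSE))
  f2 <- inter_patient_scan(scan_repository(man2$root), "DP1")
  expect_equal(f2$n_comparisons, 0)
})

test_that("relaxing the grade never removes flags (threshold monotonicity)", {
  man <- local_repo(qc_sim_params(seed = 35, providers = 1,
                                  patients_per_provider = 6,
                                  cancer_mix = c(lung = 1),
                                  include_masks = FALSE,
                                  rates = list(duplicate_series_intra = 1 / 6)))
  idx <- scan_repository(man$root)
  hi <- intra_scan_all(idx, grade = "high", ruleset = rs)
  no <- intra_scan_all(idx, grade = "normal", ruleset = rs)
  key <- function(f) with(f$pairs[f$pairs$flagged, ], paste(series_a, series_b))
  expect_true(all(key(hi) %in% key(no)))
})

test_that("similarity percentage reproduces the reported example scores", {
  expect_equal(similarity_percentage(110, 119), 92.44)
  expect_equal(similarity_percentage(4, 105), 3.81)
  expect_equal(similarity_percentage(7, 7), 100)
  expect_true(is.na(similarity_percentage(0, 0)))
})

test_that("findings stratify by timepoint gap", {
  man <- local_repo(qc_sim_params(seed = 36, providers = 1,
                                  patients_per_provider = 4, timepoints = 2,
                                  cancer_mix = c(lung = 1),
                                  include_masks = FALSE,
                                  rates = list(duplicate_series_inter = 0.5)))
  idx <- scan_repository(man$root)
  f <- inter_patient_scan(idx, "DP1", grade = "high", ruleset = rs)
  tab <- stratify_by_timepoint_gap(f)
  expect_setequal(tab$gap, c("0", "1"))
  expect_equal(sum(tab$comparisons), f$n_comparisons)
  # planted inter duplicates sit at T1 in both patients: gap 0
  expect_equal(tab$flagged[tab$gap == "0"],
               nrow(man$defects$duplicate_series_inter))
  empty <- stratify_by_timepoint_gap(intra_patient_scan(idx, "DP1",
                                                        "nonexistent"))
  expect_equal(nrow(empty), 0)
})
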
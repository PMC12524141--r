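rs <- load_ruleset()

test_that("label vocabulary checks accept known and reject unknown codes", {
  mg <- lookup_vocabulary(rs, "breast", "MG")
  mr <- lookup_vocabulary(rs, "breast", "MR")
  a14 <- annotation_from_array(array(c(0L, 1L, 4L, 0L), c(2, 2)))
  expect_equal(nrow(check_label_vocabulary(a14, mg)), 0)   # MG allows 1-6
  a5 <- annotation_from_array(array(c(0L, 5L), c(1, 2)))
  v <- check_label_vocabulary(a5, mr)                      # MR allows 1-3
  expect_equal(v$label, 5L)
  expect_equal(v$voxels, 1L)
  zeros <- annotation_from_array(array(0L, c(4, 4, 2)))
  expect_equal(nrow(check_label_vocabulary(zeros, mr)), 0)
  expect_error(check_label_vocabulary(a5, NULL), "vocabulary")
})

test_that("geometry consistency distinguishes ROI and slice mismatches", {
  a <- annotation_from_array(array(0L, c(512, 512, 100)))
  expect_equal(check_geometry_consistency(a, series_dims = c(512, 512, 100))$status,
               "consistent")
  expect_equal(check_geometry_consistency(a, series_dims = c(512, 512, 120))$status,
               "slice_mismatch")
  b <- annotation_from_array(array(0L, c(256, 256, 100)))
  expect_equal(check_geometry_consistency(b, series_dims = c(512, 512, 120))$status,
               "both_mismatch")
  expect_equal(check_geometry_consistency(b, series_dims = c(512, 512, 100))$status,
               "roi_mismatch")
})

test_that("empty-annotation detection is exact", {
  expect_true(is_empty_annotation(annotation_from_array(array(0L, c(8, 8, 3)))))
  one <- array(0L, c(8, 8, 3)); one[4, 4, 2] <- 1L
  expect_false(is_empty_annotation(annotation_from_array(one)))
})

test_that("planted mismatch and empty rates are recovered exactly", {
  man <- local_repo(qc_sim_params(seed = 41, providers = 1,
                                  patients_per_provider = 10,
                                  rates = list(mask_slice_mismatch = 0.3,
                                               mask_roi_mismatch = 0.1,
                                               empty_mask = 0.3)))
  idx <- scan_repository(man$root)
  ac <- annotation_consistency(idx)
  expect_equal(ac$metric$percentage, man$expected$annotation_consistency)
  expect_equal(ac$metric$percentage, 60)   # 1 - (0.3 + 0.1)
  expect_equal(ac$empty_pct, 30)
  expect_equal(sum(ac$statuses$status == "slice_mismatch"), 6)
  expect_equal(sum(ac$statuses$status %in% c("roi_mismatch", "both_mismatch")), 2)
})

test_that("timepoint coverage counts patients by distinct annotated timepoints", {
  d <- withr::local_tempdir()
  put <- function(pat, tp, mod = "MR") {
    sd <- file.path(d, "DP1", pat, sprintf("T%d", tp), mod, "S1")
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    dicom_write(file.path(sd, "I001.dcm"), list(Modality = mod),
                pixels = noise_image(8, tp))
    RNifti::writeNifti(array(0L, c(8, 8, 1)),
                       file.path(dirname(sd), "S1_annotation.nii.gz"))
  }
  # planted coverage {1 timepoint: 2 patients, 2 timepoints: 1, 3: 1}
  put("P1", 1); put("P2", 1)
  put("P3", 1); put("P3", 2)
  put("P4", 1); put("P4", 2); put("P4", 3)
  idx <- scan_repository(d)
  cov <- timepoint_coverage(idx, c(P1 = "prostate", P2 = "prostate",
                                   P3 = "prostate", P4 = "prostate"))
  expect_equal(cov$patients[cov$timepoints == 1], 2)
  expect_equal(cov$patients[cov$timepoints == 2], 1)
  expect_equal(cov$patients[cov$timepoints == 3], 1)
  # row sums equal the number of annotated patients
  expect_equal(sum(cov$patients), 4)
})

test_that("label class summary reconstructs reported malignant/benign shares", {
  vocab <- lookup_vocabulary(rs, "lung", "CT")
  anns <- c(lapply(seq_len(305), function(i)
    annotation_from_array(array(c(0L, 3L), c(1, 2)))),
    lapply(seq_len(5), function(i)
      annotation_from_array(array(c(0L, 1L), c(1, 2)))))
  s <- label_class_summary(anns, vocab)
  expect_equal(s$n, 310)
  expect_equal(s$malignant_pct, 98.4)
  expect_equal(s$benign_pct, 1.6)
  # malignant + benign shares close on 100 when no other-class labels exist
  expect_lte(abs(s$malignant_pct + s$benign_pct - 100), 0.1)
})

test_that("other-class labels dilute the denominator but not the numerators", {
  vocab <- lookup_vocabulary(rs, "breast", "MG")
  only_other <- lapply(1:4, function(i)
    annotation_from_array(array(c(0L, 4L), c(1, 2))))   # calcification
  expect_warning(s0 <- label_class_summary(list(), vocab), "no labeled")
  s <- label_class_summary(only_other, vocab)
  expect_equal(s$malignant_pct, 0)
  expect_equal(s$benign_pct, 0)
  expect_equal(s$n, 4)
  # a mask contributes once per distinct nonzero label code
  multi <- annotation_from_array(array(c(1L, 3L, 3L, 4L), c(2, 2)))
  s2 <- label_class_summary(list(multi), vocab)
  expect_equal(s2$n, 3)
})

test_that("coverage row sums match annotated patients on generated repos", {
  man <- local_repo(qc_sim_params(seed = 42, providers = 2,
                                  patients_per_provider = 5))
  idx <- scan_repository(man$root)
  clin <- load_clinical_tables(man$root, rs)
  cov <- timepoint_coverage(idx, setNames(clin$cancer_type, clin$patient_id))
  # every patient is annotated at both timepoints for one modality
  expect_true(all(cov$timepoints == 2))
  expect_equal(sum(cov$patients), 10)
})
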
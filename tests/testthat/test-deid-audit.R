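rs <- load_ruleset()

test_that("retained forbidden attributes yield one violation per tag per instance", {
  inst <- rbind(fake_instance("f1.dcm", patient_sex = "M"),
                fake_instance("f2.dcm"),
                fake_instance("f3.dcm", patient_sex = "F", patient_age = "061Y"))
  v <- audit_removed_attributes(inst, rs$deid)
  expect_equal(nrow(v), 3)
  expect_equal(sum(v$detail == "PatientSex"), 2)
  expect_equal(sum(v$detail == "PatientAge"), 1)
  clean <- audit_removed_attributes(rbind(fake_instance("g1.dcm")), rs$deid)
  expect_equal(nrow(clean), 0)
})

test_that("date hashing audit flags wrong ids and inconsistent visit dates", {
  # consistent: one hashed date across the visit, header id = folder id
  ok <- do.call(rbind, lapply(1:5, function(i)
    fake_instance(sprintf("a%d.dcm", i), study_date = "20200315")))
  expect_equal(nrow(audit_date_hashing(ok, "P001", rs$deid)), 0)
  # a file hashed with a different patient's id
  wrong <- rbind(fake_instance("b1.dcm", study_date = "20200315"),
                 fake_instance("b2.dcm", study_date = "20200315",
                               header_patient_id = "P999"))
  v <- audit_date_hashing(wrong, "P001", rs$deid)
  expect_equal(v$file, "b2.dcm")
  expect_match(v$detail, "P999")
  # one file of five shifted by one day breaks offset consistency
  skew <- do.call(rbind, lapply(1:5, function(i)
    fake_instance(sprintf("c%d.dcm", i),
                  study_date = if (i == 4) "20200316" else "20200315")))
  v2 <- audit_date_hashing(skew, "P001", rs$deid)
  expect_equal(v2$file, "c4.dcm")
  expect_match(v2$category, "date_hash_mismatch")
})

test_that("the per-patient date offset is deterministic and bounded", {
  o1 <- date_offset_days("P0001")
  expect_identical(o1, date_offset_days("P0001"))
  offs <- date_offset_days(sprintf("P%04d", 1:50))
  expect_true(all(offs >= 0 & offs < 365))
  expect_gt(length(unique(offs)), 1)
})

test_that("burnt-in screening is recall-oriented on header hints", {
  inst <- rbind(fake_instance("h1.dcm", burned_in = "YES"),
                fake_instance("h2.dcm", readable = FALSE))
  cand <- screen_burnt_in_candidates(inst, rs$report_classifier)
  expect_setequal(cand$reason, c("burned_in_annotation_tag",
                                 "unreadable_pixels"))
})

test_that("the color-spectrum classifier separates reports from organ depictions", {
  # all-white page: 100% background
  expect_equal(classify_report_image(matrix(255, 64, 64)), "report")
  # degenerate constant image is all background
  expect_equal(classify_report_image(matrix(0, 32, 32)), "report")
  # synthetic text page: white background, black glyph runs
  set.seed(6)
  txt <- cimqc:::report_image(64)
  expect_equal(classify_report_image(txt), "report")
  # smooth elliptical phantom with noise: rich spectrum
  ph <- cimqc:::phantom_image(64)
  expect_equal(classify_report_image(ph), "organ")
  # full-range smooth gradient: > 64 distinct levels
  grad <- outer(1:64, 1:64, function(i, j) (i + j) * 2)
  expect_equal(classify_report_image(grad), "organ")
})

test_that("planted de-id violations are fully detected with no false positives", {
  man <- local_repo(qc_sim_params(seed = 44, providers = 1,
                                  patients_per_provider = 25, timepoints = 1,
                                  include_masks = FALSE,
                                  rates = list(retained_sex_tag = 0.12,
                                               retained_age_tag = 0.12,
                                               date_hash_wrong_id = 0.08,
                                               burnt_in_report = 0.08)))
  idx <- scan_repository(man$root)
  aud <- deid_audit(idx, rs)
  pats <- man$patients
  files_of <- function(ids)
    idx$instances$file[idx$instances$patient_id %in% pats$patient_id[ids]]
  v <- aud$violations
  expect_setequal(v$file[v$category == "retained_attribute" &
                           v$detail == "PatientSex"],
                  files_of(man$defects$retained_sex_tag))
  expect_setequal(v$file[v$category == "retained_attribute" &
                           v$detail == "PatientAge"],
                  files_of(man$defects$retained_age_tag))
  expect_setequal(v$file[v$category == "date_hash_mismatch"],
                  files_of(man$defects$date_hash_wrong_id))
  expect_equal(sum(v$category == "burnt_in_report"),
               length(man$defects$burnt_in_report))
  # every violating file was planted; the compliant complement is untouched
  planted <- unique(c(files_of(c(man$defects$retained_sex_tag,
                                 man$defects$retained_age_tag,
                                 man$defects$date_hash_wrong_id)),
                      v$file[v$category == "burnt_in_report"]))
  expect_setequal(unique(v$file), planted)
})

test_that("anonymization metric counts non-conformant files once each", {
  man <- local_repo(qc_sim_params(seed = 45, providers = 1,
                                  patients_per_provider = 10,
                                  include_masks = FALSE,
                                  rates = list(retained_sex_tag = 0.1)))
  idx <- scan_repository(man$root)
  am <- anonymization_metric(idx, rs)
  expect_equal(am$metric$percentage, 90)
  expect_equal(am$metric$denominator, man$counts$files)
  # fully compliant repository: 100% conformant, no report images either
  man0 <- local_repo(qc_sim_params(seed = 46, providers = 1,
                                   patients_per_provider = 5,
                                   include_masks = FALSE))
  am0 <- anonymization_metric(scan_repository(man0$root), rs)
  expect_equal(am0$metric$percentage, 100)
  expect_equal(sum(am0$audit$violations$category == "burnt_in_report"), 0)
})

test_that("audits never modify input files", {
  man <- local_repo(qc_sim_params(seed = 47, providers = 1,
                                  patients_per_provider = 4,
                                  rates = list(retained_sex_tag = 0.25,
                                               burnt_in_report = 0.25)))
  files <- list.files(man$root, recursive = TRUE, full.names = TRUE)
  before <- tools::md5sum(files)
  idx <- scan_repository(man$root)
  invisible(anonymization_metric(idx, rs))
  invisible(intra_scan_all(idx))
  after <- tools::md5sum(files)
  expect_identical(before, after)
})
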
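rs <- load_ruleset()

test_that("completeness counts patients with full mandatory fields and follow-up", {
  # 10 patients: 3 missing a mandatory field, 1 other with only-diagnosis
  # imaging -> 6/10 = 60.00%
  tbl <- make_clinical(
    patient_id = sprintf("P%02d", 1:10), provider = "DP1",
    cancer_type = "lung", sex = "M", age = "60",
    histological_type = "Adenocarcinoma", grade = "2",
    stage = c(rep("II", 7), NA, NA, NA), biopsy = "Biopsy")
  ser <- do.call(rbind, lapply(sprintf("P%02d", 1:10), function(p)
    rbind(fake_series_row(p, 1L, "CT"),
          if (p != "P07") fake_series_row(p, 2L, "CT"))))
  m <- completeness(tbl, fake_index(ser), rs)
  expect_equal(m$percentage, 60)
  expect_equal(m$denominator, 10)
  expect_match(m$flags$reason[m$flags$record == "P07"], "no_followup_timepoint")
  expect_match(m$flags$reason[m$flags$record == "P08"], "missing:stage")
})

test_that("a patient absent from the index fails the follow-up condition", {
  tbl <- make_clinical(patient_id = c("P1", "P2"), provider = "DP1",
                       cancer_type = "lung", sex = "M", age = "61",
                       histological_type = "x", grade = "1", stage = "I",
                       biopsy = "Biopsy")
  ser <- rbind(fake_series_row("P1", 1L, "CT"), fake_series_row("P1", 2L, "CT"))
  m <- completeness(tbl, fake_index(ser), rs)
  expect_equal(m$numerator, 1)
  expect_match(m$flags$reason[m$flags$record == "P2"], "patient_not_in_index")
})

test_that("validity counts each inserted value; missing values stay out", {
  # 20 inserted values over sex/age/grade/stage, 5 invalid -> 75.00%
  tbl <- make_clinical(
    patient_id = sprintf("V%02d", 1:5), provider = "DP1",
    sex = c("M", "F", "Female", "M", "F"),       # 1 invalid
    age = c("64", "200", "59", "-3", "71"),      # 2 invalid
    grade = c("2", "2", "9", "1", "3"),          # 1 invalid
    stage = c("I", "III", "3", "IV", "II"))      # 1 invalid ("3" not III)
  m <- validity(tbl, rs)
  expect_equal(m$denominator, 20)
  expect_equal(m$numerator, 15)
  expect_equal(m$percentage, 75)
  # blanking a value removes it from the denominator entirely
  tbl$age[1] <- NA
  m2 <- validity(tbl, rs)
  expect_equal(m2$denominator, 19)
})

test_that("an all-missing table leaves validity undefined, never 0 or 100", {
  tbl <- make_clinical(patient_id = c("A", "B"),
                       sex = c(NA, NA), age = c(NA, NA))
  m <- validity(tbl, rs)
  expect_equal(m$denominator, 0)
  expect_true(is.na(m$percentage))
})

test_that("consistency evaluates cross-link rules per applicable patient", {
  # 8 applicable evaluations, 2 failing -> 75.00%
  tbl <- make_clinical(
    patient_id = sprintf("C%02d", 1:9),
    biopsy = c(rep("Biopsy", 4), "No Biopsy", "No Biopsy",
               "No Biopsy", "No Biopsy", NA),
    er_status = c(rep("Positive", 4), "Positive", "Negative", NA, NA, "Positive"),
    pr_status = c(rep("Negative", 4), NA, NA, NA, NA, NA))
  m <- consistency(tbl, rs)
  expect_equal(m$denominator, 8)   # the NA-biopsy patient is not applicable
  expect_equal(m$numerator, 6)
  expect_equal(m$percentage, 75)
})

test_that("consistency without rules is undefined with a warning", {
  rs0 <- rs
  rs0$crosslink_rules <- list()
  tbl <- make_clinical(patient_id = "P1", biopsy = "Biopsy")
  expect_warning(m <- consistency(tbl, rs0), "no crosslink")
  expect_true(is.na(m$percentage))
})

test_that("integrity fails declaration mismatches in both directions", {
  # MG declared, CT provided -> both records fail
  tbl <- make_clinical(patient_id = "P1", provider = "DP1",
                       modalities_t1 = "MG")
  idx <- fake_index(fake_series_row("P1", 1L, "CT"))
  m <- integrity(tbl, idx, rs)
  expect_equal(m$denominator, 2)
  expect_equal(m$numerator, 0)
  expect_setequal(m$flags$reason, c("undeclared_modality",
                                    "declared_modality_absent"))
})

test_that("integrity flags count mismatches and passes exact matches", {
  # 3 declared, 4 provided -> one count-mismatch failure
  tbl <- make_clinical(patient_id = "P1", provider = "DP1",
                       modalities_t1 = "CT;CT;CT")
  ser <- do.call(rbind, lapply(1:4, function(i)
    fake_series_row("P1", 1L, "CT", series_id = paste0("S", i))))
  m <- integrity(tbl, fake_index(ser), rs)
  expect_equal(m$flags$reason, "count_mismatch")
  # exact declaration, conforming names -> 100.00%
  tbl2 <- make_clinical(patient_id = "P1", provider = "DP1",
                        modalities_t1 = "CT;MG", modalities_t2 = "CT")
  ser2 <- rbind(fake_series_row("P1", 1L, "CT"),
                fake_series_row("P1", 1L, "MG", series_id = "S2"),
                fake_series_row("P1", 2L, "CT"))
  m2 <- integrity(tbl2, fake_index(ser2), rs)
  expect_equal(m2$percentage, 100)
  expect_equal(m2$denominator, 3)
})

test_that("integrity fails naming violations even when declared correctly", {
  tbl <- make_clinical(patient_id = "P1", provider = "DP1",
                       modalities_t1 = "CT")
  m <- integrity(tbl, fake_index(fake_series_row("P1", 1L, "CT",
                                                 naming_ok = FALSE)), rs)
  expect_equal(m$flags$reason, "naming_violation")
})

test_that("injected defect classes act independently on their own dimension", {
  man <- local_repo(qc_sim_params(seed = 9, providers = 1,
                                  patients_per_provider = 20,
                                  rates = list(invalid_value = 0.2)))
  idx <- scan_repository(man$root)
  clin <- load_clinical_tables(man$root, rs)
  expect_equal(completeness(clin, idx, rs)$percentage, 100)
  expect_equal(consistency(clin, rs)$percentage, 100)
  expect_equal(integrity(clin, idx, rs)$percentage, 100)
  expect_equal(validity(clin, rs)$percentage, man$expected$validity)
  expect_lt(validity(clin, rs)$percentage, 100)
})

test_that("raising a defect rate never increases the affected metric", {
  pcts <- vapply(c(0, 0.1, 0.3), function(p) {
    man <- local_repo(qc_sim_params(seed = 12, providers = 1,
                                    patients_per_provider = 10,
                                    rates = list(missing_mandatory = p)))
    idx <- scan_repository(man$root)
    clin <- load_clinical_tables(man$root, rs)
    completeness(clin, idx, rs)$percentage
  }, 0)
  expect_true(all(diff(pcts) <= 0))
  expect_equal(pcts, c(100, 90, 70))
})
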
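rs <- load_ruleset()

test_that("age bins are left-open right-closed with overflow bins", {
  expect_equal(assign_age_bin(25), "(20, 25]")
  expect_equal(assign_age_bin(26), "(25, 30]")
  expect_equal(assign_age_bin(20), "<=20")
  expect_equal(assign_age_bin(19), "<=20")
  expect_equal(assign_age_bin(95), "(90, 95]")
  expect_equal(assign_age_bin(96), ">95")
  expect_warning(b <- assign_age_bin(-4), "negative")
  expect_true(is.na(b))
})

test_that("sex distribution reconstructs the printed two-class cells", {
  # 47 male / 33 female -> 58.75% / 41.25%
  tbl <- make_clinical(patient_id = sprintf("P%03d", 1:80), provider = "DP3",
                       cancer_type = "colorectal",
                       sex = c(rep("M", 47), rep("F", 33)))
  d <- subgroup_distribution(tbl, "sex", "DP3", rs)
  expect_equal(d$classes$percentage[d$classes$class == "M"], 58.75)
  expect_equal(d$classes$percentage[d$classes$class == "F"], 41.25)
  expect_equal(d$n, 80)
})

test_that("grade distributions reconstruct printed three-class cells", {
  # colorectal 8/5/1 over grades 1-3 -> 57.14 / 35.71 / 7.14
  tbl <- make_clinical(patient_id = sprintf("P%02d", 1:14), provider = "DP1",
                       cancer_type = "colorectal",
                       grade = c(rep("1", 8), rep("2", 5), "3"))
  d <- subgroup_distribution(tbl, "cancer_grade", "DP1", rs)
  expect_equal(d$classes$percentage, c(57.14, 35.71, 7.14))
  # lung 4/3 over grades 2-3 -> 57.14 / 42.86, grade 1 listed with zero count
  tb2 <- make_clinical(patient_id = sprintf("L%02d", 1:7), provider = "DP2",
                       cancer_type = "lung",
                       grade = c(rep("2", 4), rep("3", 3)))
  d2 <- subgroup_distribution(tb2, "cancer_grade", "DP2", rs)
  expect_equal(d2$classes$percentage, c(0, 57.14, 42.86))
  expect_equal(d2$classes$count[1], 0)
})

test_that("age-bin distributions reconstruct printed table columns", {
  # 28 breast patients across bins: 3.57 / 7.14 / ... / 17.86 pattern
  ages <- c(33, 38, 38, 48, 48, 48, 48, 53, 53, 58, 58, 58, 63, 63, 63, 63,
            68, 68, 68, 73, 73, 73, 78, 78, 78, 78, 78, 83)
  tbl <- make_clinical(patient_id = sprintf("B%02d", 1:28), provider = "DP1",
                       cancer_type = "breast", age = as.character(ages))
  d <- subgroup_distribution(tbl, "age_bin", "DP1", rs)
  cells <- setNames(d$classes$percentage, d$classes$class)
  expect_equal(unname(cells["(30, 35]"]), 3.57)
  expect_equal(unname(cells["(35, 40]"]), 7.14)
  expect_equal(unname(cells["(45, 50]"]), 14.29)
  expect_equal(unname(cells["(55, 60]"]), 10.71)
  expect_equal(unname(cells["(75, 80]"]), 17.86)
  expect_equal(unname(cells["(40, 45]"]), 0)
  # 9 lung patients: 1/2/1/0/2/3 over six bins
  ages2 <- c(53, 58, 58, 63, 73, 73, 78, 78, 78)
  tb2 <- make_clinical(patient_id = sprintf("L%02d", 1:9), provider = "DP1",
                       cancer_type = "lung", age = as.character(ages2))
  d2 <- subgroup_distribution(tb2, "age_bin", "DP1", rs)
  c2 <- setNames(d2$classes$percentage, d2$classes$class)
  expect_equal(unname(c2[c("(50, 55]", "(55, 60]", "(60, 65]", "(65, 70]",
                           "(70, 75]", "(75, 80]")]),
               c(11.11, 22.22, 11.11, 0, 22.22, 33.33))
})

test_that("distributions are permutation invariant and counts sum to n", {
  tbl <- make_clinical(patient_id = sprintf("P%02d", 1:30), provider = "DP1",
                       cancer_type = "lung",
                       sex = rep(c("M", "F", "M"), 10))
  d1 <- subgroup_distribution(tbl, "sex", "DP1", rs)
  set.seed(4); tbl2 <- tbl[sample(30), ]
  d2 <- subgroup_distribution(tbl2, "sex", "DP1", rs)
  expect_equal(d1$classes, d2$classes)
  expect_equal(sum(d1$classes$count), d1$n)
  expect_lte(abs(sum(d1$classes$percentage) - 100), 0.05)
})

test_that("missing values leave the denominator and are reported alongside", {
  tbl <- make_clinical(patient_id = c("A", "B", "C", "D"), provider = "DP1",
                       cancer_type = "lung", sex = c("M", NA, "F", NA))
  d <- subgroup_distribution(tbl, "sex", "DP1", rs)
  expect_equal(d$n, 2)
  expect_equal(d$n_missing, 2)
  expect_equal(d$classes$percentage, c(50, 50))
})

test_that("fairness report flags dominance, absence and missing variables", {
  tbl <- make_clinical(
    patient_id = sprintf("P%02d", 1:20), provider = "DP1",
    cancer_type = "lung", sex = c(rep("M", 19), "F"),
    age = as.character(seq(45, 83, 2)), grade = NA_character_)
  fr <- fairness_report(tbl, rs)
  f <- fr$flags
  expect_true(any(f$flag == "dominance" & f$variable == "sex"))     # 19 vs 1
  expect_true(any(f$flag == "variable_missing" & f$variable == "cancer_grade"))
  # a balanced two-class site raises no sex flags
  tb2 <- make_clinical(patient_id = sprintf("Q%02d", 1:10), provider = "DP2",
                       cancer_type = "lung", sex = rep(c("M", "F"), 5),
                       age = as.character(seq(50, 68, 2)), grade = "2")
  f2 <- fairness_report(tb2, rs)$flags
  expect_false(any(f2$variable == "sex" & f2$flag %in%
                     c("dominance", "absent_subgroup")))
})

test_that("structurally fixed variables are not flagged (prostate sex)", {
  tbl <- make_clinical(patient_id = sprintf("P%02d", 1:10), provider = "DP1",
                       cancer_type = "prostate", sex = "M",
                       age = as.character(seq(55, 73, 2)), grade = "2")
  f <- fairness_report(tbl, rs)$flags
  expect_false(any(f$variable == "sex"))
})

test_that("per-class counts across sites sum to the global count", {
  man <- local_repo(qc_sim_params(seed = 21, providers = 3,
                                  patients_per_provider = 10))
  clin <- load_clinical_tables(man$root, rs)
  per_site <- lapply(unique(clin$provider), function(s)
    subgroup_distribution(clin, "sex", s, rs)$classes)
  tot <- subgroup_distribution(clin, "sex", NULL, rs)$classes
  summed <- Reduce(`+`, lapply(per_site, `[[`, "count"))
  expect_equal(summed, tot$count)
})
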
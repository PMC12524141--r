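# Shared fixture builders. Everything is generated in code at test time;
# nothing binary ships with the package.

make_clinical <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  structure(df, class = c("qc_clinical", "data.frame"))
}

# a minimal index containing just the series table (what the clinical
# dimensions consume); instances/annotations empty
fake_series_row <- function(patient_id, timepoint, modality,
                            naming_ok = TRUE, provider = "DP1",
                            series_id = "S1", n_instances = 1L) {
  data.frame(provider = provider, patient_id = patient_id,
             timepoint = timepoint, modality = modality,
             modality_dir = modality, naming_ok = naming_ok,
             series_id = series_id, path = NA_character_,
             n_instances = n_instances, mask_path = NA_character_,
             stringsAsFactors = FALSE)
}

fake_index <- function(series) {
  pats <- unique(series[c("provider", "patient_id")])
  structure(list(root = ".", patients = pats, series = series,
                 instances = data.frame(), annotations = data.frame(),
                 skipped = data.frame(), warnings = character()),
            class = "qc_repo_index")
}

# an instances data.frame row as read_series_header() would produce
fake_instance <- function(file, patient_id = "P001", timepoint = 1L,
                          modality = "CT", provider = "DP1",
                          uid = NA, sop_class = NA, header_modality = "CT",
                          study_date = NA, header_patient_id = patient_id,
                          patient_sex = NA, patient_age = NA,
                          patient_name = NA, patient_birth_date = NA,
                          burned_in = NA, readable = TRUE) {
  data.frame(file = file, readable = readable, uid = as.character(uid),
             sop_class = as.character(sop_class),
             header_modality = header_modality,
             rows = 32, cols = 32, pixel_spacing_row = 1,
             pixel_spacing_col = 1, slice_thickness = 3,
             manufacturer = "GE", field_strength = NA_real_,
             convolution_kernel = NA_character_,
             scanning_sequence = NA_character_,
             patient_sex = as.character(patient_sex),
             patient_age = as.character(patient_age),
             patient_name = as.character(patient_name),
             patient_birth_date = as.character(patient_birth_date),
             header_patient_id = header_patient_id,
             study_date = as.character(study_date),
             burned_in = as.character(burned_in),
             provider = provider, patient_id = patient_id,
             timepoint = timepoint, modality = modality, series_id = "S1",
             stringsAsFactors = FALSE)
}

# deterministic noise image on [0, 255]
noise_image <- function(n = 64, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}

local_repo <- function(params, env = parent.frame()) {
  root <- tempfile("qcrepo_test")
  withr::defer(unlink(root, recursive = TRUE), envir = env)
  generate_repository(params, root = root)
}
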
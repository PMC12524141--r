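# Default quality rule-set.
#
# Encodes the rule ledger every dimension is parameterized by: mandatory
# clinical fields per cancer type, per-field value rules, cross-link rules,
# modality declaration columns, annotation label vocabularies, the
# de-identification profile, deduplication thresholds and fairness binning.
# All entries are overridable; this file is the documented default.

layout:
  timepoint_pattern: "^T([0-9]+)$"
  mask_suffix: "_annotation"

modality_codes: [CT, MR, MG, US, PT, FUSCT, FUSPT, XRAY]

missing_sentinels: ["", "na", "n/a", "null"]

cancer_types: [breast, lung, colorectal, prostate]

mandatory_fields:
  default: [sex, age, cancer_type, histological_type, grade, stage, biopsy]

field_rules:
  cancer_type: {type: categorical, allowed: [breast, lung, colorectal, prostate]}
  study_phase: {type: categorical, allowed: [retrospective, prospective, observational]}
  sex:         {type: categorical, allowed: [M, F]}
  age:         {type: integer, min: 0, max: 120}
  grade:       {type: integer, min: 1, max: 5}
  stage:       {type: categorical, allowed: [I, II, III, IV]}
  histological_type: {type: free-text}
  biopsy:      {type: categorical, allowed: [Biopsy, No Biopsy]}
  er_status:   {type: categorical, allowed: [Positive, Negative]}
  pr_status:   {type: categorical, allowed: [Positive, Negative]}

crosslink_rules:
  # biomarker results must not be present when no biopsy was performed
  - name: biopsy_biomarkers
    condition_field: biopsy
    condition_equals: "No Biopsy"
    require_missing: [er_status, pr_status]

modality_declarations:
  column_pattern: "^modalities_t([0-9]+)$"
  separator: ";"

integrity:
  include_declared_absent: true

dedup:
  thresholds: {high: 0.1, normal: 10.0}
  resample_size: 64
  cross_pair_cap: 200

fairness:
  variables: [sex, age_bin, cancer_type, cancer_grade]
  age_bin: {start: 20, end: 95, width: 5}
  dominance_share: 0.8
  grade_levels:
    default: [1, 2, 3]
    prostate: [1, 2, 3, 4, 5]
  structurally_fixed:
    prostate: [sex]

annotated_modalities:
  breast: [CT, FUSCT, FUSPT, MG, MR, US]
  lung: [CT, FUSCT, FUSPT, XRAY]
  colorectal: [CT, FUSCT, FUSPT, MR]
  prostate: [MR]

label_vocabulary:
  # mammography lesion classes agreed at data collection
  breast:
    MG:
      - {code: 1, name: Benign, class: benign}
      - {code: 2, name: Suspicious or Indeterminate, class: other}
      - {code: 3, name: Malignant, class: malignant}
      - {code: 4, name: Calcification, class: other}
      - {code: 5, name: Surgical clip, class: other}
      - {code: 6, name: Axial lymph node, class: other}
    MR:
      - {code: 1, name: Benign, class: benign}
      - {code: 2, name: Suspicious or Indeterminate, class: other}
      - {code: 3, name: Malignant, class: malignant}
  # other cancer/modality vocabularies are site configuration; the default
  # three-class scheme applies where no specific list is given
  default:
    - {code: 1, name: Benign, class: benign}
    - {code: 2, name: Suspicious or Indeterminate, class: other}
    - {code: 3, name: Malignant, class: malignant}

deid:
  forbidden_attributes: [PatientSex, PatientAge, PatientName, PatientBirthDate]
  hashed_date_attributes: [StudyDate]
  date_offset_modulus: 365

report_classifier:
  background_fraction: 0.5
  background_tolerance: 0.05
  max_distinct_levels: 64

attributes:
  CT: [slice_thickness, pixel_spacing, rows, columns, convolution_kernel, manufacturer]
  MR: [slice_thickness, pixel_spacing, rows, columns, manufacturer,
       magnetic_field_strength, scanning_sequence]
  PT: [slice_thickness, pixel_spacing, rows, columns, manufacturer]
  default: [slice_thickness, pixel_spacing, rows, columns, manufacturer]

categorical_other_floor: 0.05
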
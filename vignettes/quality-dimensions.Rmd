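---
title: "Quality dimensions for multicenter cancer-imaging repositories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality dimensions for multicenter cancer-imaging repositories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimqc)
```

## The audit model

`cimqc` treats repository quality as a battery of count-based dimensions,
each defined by a *record universe* and a *pass rule*, reported as the
percentage of passing records with a per-record reason ledger. This framing
has two consequences that shape the whole package. First, every metric is
exactly recomputable from counts — there is no estimation step, no sampling
error, and therefore the synthetic-data tests can demand exact recovery.
Second, the denominators must be defined with care, because two dimensions
must never claim the same defect:

* a **missing** value counts against *completeness* only (its patient
  record fails); it never enters the *validity* denominator;
* a **present-but-wrong** value counts against *validity* only (that value
  record fails); the patient can still be complete;
* a broken **cross-link** (e.g. biomarker results present while the biopsy
  field says "No Biopsy") counts against *consistency*, evaluated once per
  applicable rule per patient — a rule is applicable when its condition
  field is non-missing, so consistency is undefined (with a warning) on a
  table with no populated condition fields, never 0% or 100%;
* *integrity* records are modality occurrences per (patient, timepoint):
  a provided modality passes iff it is declared, the declared series count
  matches the provided count, and its directories follow the naming
  convention. Declared-but-absent modalities add failing records; this is
  switchable (`integrity$include_declared_absent`) because the alternative
  denominator convention is also defensible;
* *anonymization* records are DICOM files; a file fails iff it carries at
  least one de-identification violation of any category. The metric
  reports the **conformant** share, consistent with every other dimension;
  the non-conformant share is exposed alongside in the report.

A zero denominator always yields an undefined percentage (`NA`), never a
boundary value, so downstream consumers cannot mistake "nothing to assess"
for "perfect" or "broken".

Percentages are rounded half-up — 2 decimals for the dimension metrics and
fairness cells, 1 decimal for label-class and attribute shares — because
that is how such tables are conventionally printed; base R's
round-half-to-even would disagree on exactly the boundary cases that
count-based metrics produce.

## Tunable parameters

All tunables live in one YAML/JSON rule-set
(`inst/extdata/default_rules.yaml`), loaded by `load_ruleset()` and
validated by `check_ruleset()`:

* **Mandatory fields** (per cancer type) and **field rules** (type,
  allowed set, numeric range). Defaults cover the usual template: sex in
  {M, F}, age 0–120 years, grade 1–5, stage in Roman numerals {I–IV} (so a
  `"3"` is invalid), biopsy flag, biomarker status fields.
* **Cross-link rules**: condition field/value plus require-missing /
  require-present / require-equals clauses.
* **Dedup thresholds**: `high = 0.1` MSE on the 0–255 intensity scale —
  deliberately stringent, flagging only near-exact copies; `normal = 10.0`
  is the shipped permissive grade. Only the order (high < normal) is
  enforced; the permissive value is a judgment call for catching
  re-windowed or slightly re-encoded copies, not a derived constant.
* **Resampling grid**: 64×64 bilinear. Small enough to keep all-pairs
  scans cheap, large enough that independent noise images sit orders of
  magnitude above both thresholds (uniform-noise pairs land near
  255²/6 ≈ 10 800).
* **Age bins**: left-open right-closed 5-year bins from 20 to 95 with
  `<=20` / `>95` overflow bins, matching the repository's published table
  layout; boundary ages fall in the lower bin's closed end (25 is in
  `(20, 25]`).
* **Dominance share** (fairness): 0.8. No numeric imbalance threshold is
  established in this field; 0.8 is a documented default chosen so that a
  19-vs-1 site trips the flag while a 60/40 split does not. Variables that
  are structurally single-class for a cancer type (sex in prostate
  cancer) are configured as fixed and never flagged.
* **De-identification profile**: forbidden attributes (patient sex, age,
  name, birth date), hashed-date attributes, and the offset modulus
  (365 days).
* **Report classifier**: background fraction ≥ 0.5 within ±5% of full
  range around the modal intensity, AND ≤ 64 distinct 8-bit levels.

## Numerical and procedural choices

**Slice pairing.** For a series pair, equal-length series are compared
index-aligned — one comparison per slice position — so an identical pair
scores a similarity percentage of 100 and an *n*-slice pair contributes
*n* comparisons, which is the arithmetic behind published per-pair scores
such as 110/119 = 92.44%. Unequal-length series compare all cross pairs
while both stay at or below the configurable cap (200 slices), catching
offset or partial copies; above the cap they align over the shorter
series. The cap exists because cross-pairing is quadratic and pixel
conversion is the expensive step.

**Intensity normalization.** Pixel comparison applies rescale
slope/intercept, then per-image min–max to [0, 255]. A constant image
min-max-scales to all zeros (documented degenerate case); two constant
images therefore compare equal, which is the desired behavior for blank
secondary captures.

**Report/organ classification.** The classifier is a two-threshold
histogram heuristic, literally implementing a "color spectrum" test: text
pages are near-binary with a dominant background; organ depictions carry a
broad, dense spectrum. A degenerate constant image classifies as a report
(it is all background). OCR is an extension point, not a dependency. The
screening stage before it is recall-oriented — header hints
(burned-in-annotation tag, secondary-capture SOP class, modality OT) or
the pixel screen make a file a *candidate*; only classifier-confirmed
candidates become violations.

**Hashed-date audit.** The convention: every date tag of a patient is the
original date plus a per-patient offset in days, derived deterministically
from the patient id (polynomial hash modulo 365 — chosen to be fully
reproducible in base R and irrelevant to the audit's power, since the audit
never needs the true original date). Two checks are implementable without
ground truth and both are performed: the in-header patient id must equal
the folder-derived id, and all files of one (patient, timepoint) must share
one date — a common offset preserves within-visit equality, so a deviating
file reveals a broken or inconsistent offset. The modal date is the
reference; ties resolve to the earliest date.

**Label-class summary.** The counting unit is one label instance — a
(mask file, distinct nonzero label code) pair — because connected-component
counting is not reproducible without a morphology convention. The
denominator *n* includes label instances of classes tagged neither
malignant nor benign (calcifications, clips, lymph nodes), so M% + B% can
legitimately fall below 100 for modalities with many auxiliary labels;
with no "other" labels present they sum to 100 within rounding.

**Quartiles.** `median [q1 q3]` profiles use linearly interpolated order
statistics (the common type-7 convention), switchable to nearest-rank; no
convention is canonical for acquisition-attribute tables, and the test
suite pins the choice against an independent textbook-formula oracle.

**Determinism.** Scans order paths with locale-independent radix sorting,
reports carry no wall-clock timestamps, and the generator drives every
choice from one seed — so the same tree and configuration produce
byte-identical JSON reports, which the tests assert at the byte level.

## What the synthetic generator emulates — and what it does not

`generate_repository()` writes a complete repository: part-10 DICOM series
(only the tag set the audits read), NIfTI masks, and one clinical CSV per
cancer type, under the `provider/patient/T{n}/MODALITY/SERIES` layout. Its
defaults are the baseline study conditions used throughout the tests:
3 providers × 20 patients, the four cancer types mixed
(30/30/25/15%), two timepoints (diagnosis + one follow-up), one series of
the cancer's primary modality per timepoint, two 32×32 slices per series,
one mask per series. Demographic composition is applied with
largest-remainder rounding so configured proportions are recovered
*exactly*, not in expectation.

Fifteen defect classes are injectable at configured rates. Classes that
could perturb each other's dimension draw from disjoint patient pools
(clinical-table classes in one pool; imaging/file classes in another);
classes in different pools have distinct record universes, which keeps
every closed-form manifest expectation exact even at high rates.
Completeness defects blank two mandatory fields per affected patient, a
choice that keeps the validity denominator (10 rule-covered values per
patient) divisible at the rates exercised in the tests, so validity too
recovers `100·(1−p)` exactly rather than approximately.

What the phantoms are: smooth ellipse gradients plus uniform acquisition
noise (organ-like spectra), and near-binary text-row rasters for burnt-in
reports. What they are not: clinically realistic anatomy, scanner physics,
compression artifacts, or multi-frame/encapsulated transfer syntaxes.
Passing the recovery tests therefore demonstrates that the *counting,
linking and detection machinery* is correct under controlled conditions —
it does not certify detection power on real clinical pixel data, where
near-duplicates differ by windowing, interpolation or convolution kernel
rather than byte identity. The published experience (follow-up CTs flagged
as similar that are clinically distinct) is exactly why all findings are
advisory flags for curation, never automatic deletions.

## Problem sizes in the test suite

The suite exercises parameter recovery at 200 patients (800 files) for
defect rates 0.1/0.25/0.5, duplicate detection on 100 64×64 images with 10
planted pairs against a brute-force all-pairs oracle, the de-identification
audit on a 50-file fixture with planted violations in every category, and
annotation recovery on 100 masks; these sizes make every recovery exact
while keeping the full suite around a minute on one CPU. The acceptance
script (`scripts/acceptance.R`) re-runs the same scenarios from a
command-line seed.

## Known limitations

* DICOM parsing covers explicit-VR little-endian part-10 files with the
  audited tag set; compressed transfer syntaxes and sequences are rejected
  with a clear error rather than guessed at (such files are counted as
  non-assessable in the anonymization denominator).
* Geometry consistency compares header dimensions only; resampling masks
  onto series grids via affines is a downstream curation step.
* The report classifier is a heuristic screen; a dataset using burnt-in
  overlays on organ images (rich spectrum *and* text) would require the
  OCR extension point.
* Fairness reporting is descriptive — distributions and flags — by design;
  no scalar index, re-weighting or mitigation is computed.
* Cross-site duplicate detection (same patient submitted by two providers)
  requires cross-provider scanning, which is quadratic in repository size;
  the shipped scopes are within-patient and within-provider, matching the
  two-level screening workflow.
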
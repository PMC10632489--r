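Package: petdosim
Title: Image-Based Internal Dosimetry for PET Radiotracers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Internal radiation dosimetry from whole-body PET time-activity
    curves. Computes cumulated activity by trapezoidal integration of
    decay-uncorrected organ curves with a physical-decay (or fitted
    exponential) tail, per-organ residence times with remainder-of-body
    closure against the theoretical F-18 total of T1/2/ln2, MIRD-schema
    absorbed doses from S-value matrices, ICRP tissue-weighted effective
    dose, and regulatory compliance checks. Includes a synthetic-subject
    generator with hepatobiliary and renal excretion phenotypes whose true
    residence times are closed-form, and tools to compare two dosimetry
    pipeline variants organ by organ with sex-stratified summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
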
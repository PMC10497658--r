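Package: csfmotion
Title: Cervical CSF Flow Impedance and Cardiac-Induced Brain Tissue Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the relationship between unsteady resistance to
    cerebrospinal fluid (CSF) flow in the cervical spinal canal and
    cardiac-induced brain tissue motion. Computes hydraulic metrics of
    segmented canal cross-sections, longitudinal impedance spectra and their
    1-8 Hz integral (ILI) via a slice-wise fully developed oscillatory
    (Womersley-type) flow surrogate, decodes tissue displacement from
    phase-encoded (DENSE) MR image series, and reproduces the cohort-level
    statistical analyses (Welch tests, Pearson regression,
    displacement-cutoff subsets). Includes seeded synthetic-data generators
    for canal geometries, CSF flow waveforms, DENSE motion phantoms and
    subject cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    RNifti,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
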
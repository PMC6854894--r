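Package: trimeth
Title: Methylation Marker Discovery, Droplet Digital PCR Calling, and
    Two-of-Three ctDNA Panel Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for blood-based detection of colorectal cancer from
    circulating tumour DNA methylation. Implements discovery filtering of
    CpG candidates on 450K-style beta-value matrices, a plate-wise droplet
    digital PCR caller (minimal-bandwidth kernel density threshold on a
    fully methylated positive control, additive well normalization,
    Poisson quantification of copies per well), assay-funnel triage, input
    and recovery quality control, and the locked two-of-three TriMeth
    panel call with cohort sensitivity, specificity, stage stratification
    and empirical ROC metrics. A synthetic-data module generates
    group-structured beta matrices, bimodal droplet amplitude plates with
    per-well shifts, and stage-structured case/control plasma cohorts so
    the whole chain is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
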
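Package: ddiscreen
Title: Drug-Drug Interaction Screening for Outpatient Prescription Claims
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for screening outpatient prescription claims
    against a severity-graded drug-drug interaction knowledge base. Provides
    drug-name alias normalization with non-systemic (topical) filtering, an
    exclusion cascade with full cohort-flow accounting, per-prescription
    interaction detection and eight-category severity profiling, prevalence
    and stratified summary tables with significance tests, linear and
    logistic regression models of interaction burden with VIF diagnostics
    and case-resampling bootstrap confidence intervals, severity-coded
    interaction network export (GraphML/SIF), and a seeded synthetic-data
    generator with known ground truth so every stage is testable without
    proprietary claims or interaction-compendium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
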
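Package: methmatch
Title: Matched Two-Tissue DNA Methylation Specificity and Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for matched two-tissue DNA methylation studies
    on promoter CpG panels: probe-level quality control with zero replacement,
    probe-wise paired differential methylation with Benjamini-Hochberg
    correction and delta-beta effect classes, one-way intraclass correlation,
    sample-wise and probe-wise cross-tissue Pearson correlation stratified by
    CpG-island density class (HC/IC/LC), differential variability via
    Levene/Brown-Forsythe tests on variance-stabilized values with a
    variance-concordance band, hypergeometric enrichment and depletion of
    probe subsets across CpG density classes, and probe-wise association
    scanning of demographic variables with Storey q-value false discovery
    rate control. Includes a synthetic matched-cohort generator with planted
    effects and truth tables so every stage can be validated by parameter
    recovery without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
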
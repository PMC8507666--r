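Package: ctcpheno
Title: Single-Cell Phenotyping and Prognostic Stratification of Circulating Tumor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies single circulating tumor cells (CTCs) and CTC clusters
    from per-cell TPM expression profiles. Eliminates leukocyte and endothelial
    contaminants by marker expression and read-count quality control, assigns
    retained cells to epithelial and EMT/stem phenotype groups by hierarchical
    clustering of marker-panel signatures, cross-classifies the groups with
    chi-square adjusted-residual analysis, computes per-patient CTC-type
    detection rates with Fisher exact comparisons, and stratifies
    progression-free and overall survival by EMT-CTC burden using the
    Gehan generalized Wilcoxon test. Includes a synthetic-data generator that
    emulates CTC archetypes and CTC-count-dependent survival so the full
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
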
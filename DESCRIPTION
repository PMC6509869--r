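Package: dnbtei
Title: Dynamic Network Biomarker Detection of Treatment Pre-Stable States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies dynamic network biomarker (DNB) gene modules in
    time-course expression data spanning a control group at diagnosis,
    treated samples at ordered timepoints and a healthy reference group,
    and tracks a therapeutic effect index (TEI = CV x PCC / OPCC) across
    treatment timepoints to locate the pre-stable state, the timepoint at
    which the module's collective dynamics settle toward the healthy
    level. Provides differential expression filtering (Student's t-test
    plus fold change), control-referenced standardization, correlation
    based hierarchical clustering and composite-index module selection,
    per-timepoint thresholded correlation networks with graph export, a
    location-scale batch adjustment, and a seeded synthetic time-course
    generator with a planted module for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
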
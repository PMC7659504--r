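Package: ckindex
Title: Clinical Kinase Index: Multi-Evidence Drug-Target Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the Clinical Kinase Index (CKI), a per-gene,
    per-cohort prioritization score that integrates four lines of clinical
    evidence from tumor molecular profiles: differential overexpression in
    tumor versus normal tissue, expression-stratified overall survival
    (Kaplan-Meier curves compared by log-rank test between expression
    quartiles), residue-level mutational hotspot clustering, and
    stage-correlated expression trends across TNM, grade and stage
    classifications. Includes a synthetic cohort generator with planted
    effects for end-to-end verification, and a benchmarking module that
    compares scores against loss-of-function dependency screens via
    Kruskal-Wallis tests, Spearman correlation and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
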
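Package: ckdphen
Title: Electronic Phenotyping and Validation of Chronic Kidney Disease from Longitudinal Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based electronic phenotype algorithms for chronic kidney
    disease (KDIGO G/A staging from serum creatinine via the CKD-EPI
    equation and urine albumin-to-creatinine ratio, with temporal
    persistence rules), renal replacement therapy, type 2 diabetes,
    hypertension and cardiovascular disease, over flat per-entity extracts
    of linked electronic health records. Includes the validation machinery
    used to assess such algorithms against chart-review gold standards
    (confusion counts, sensitivity/specificity/PPV/NPV with asymptotic
    confidence intervals, Cohen's kappa, the Buderer diagnostic-accuracy
    sample-size formula, stratified validation-cohort construction, an
    administrative-code comparator), data-completeness metrics
    (documentation, breadth, density, nested completeness flags), and a
    ground-truth synthetic cohort generator so every classifier and metric
    is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
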
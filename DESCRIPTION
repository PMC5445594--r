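Package: iraps
Title: Drug-Sensitivity Gene-Expression Signatures by Iterative Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives drug-sensitivity gene-expression signatures from
    cell-line pharmacogenomic panels by iterative resampling analysis to
    predict sensitivity (IRAPS): cell lines are repeatedly half-sampled,
    classified into responders and non-responders from z-scored drug
    sensitivity values, and differentially expressed genes are collected
    per iteration; a grid search over p-value, fold-change and
    conservation-fraction thresholds then selects the weighted signature
    maximizing training ROC AUC. Includes correlation-based signature
    scoring, ROC evaluation, signature-stratified drug screens,
    optimal-cutpoint survival stratification with log-rank tests and
    delegated Cox models, Chou-Talalay median-effect synergy analysis,
    and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
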
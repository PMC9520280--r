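Package: lfqscreen
Title: Post-Processing and Covariate Screening for Label-Free Quantitative Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for post-processing label-free quantification (LFQ)
    protein-group tables from dose-response animal studies: ingest of
    MaxQuant-style tables, decoy and contaminant removal, per-condition
    low-percentile imputation of left-censored missing values, a
    replicate-completeness and peptide-evidence quantifiability filter,
    pairwise differential abundance with an empirical-Bayes moderated
    t-statistic, robust Z-scores and Benjamini-Hochberg q-values under a
    dual-criterion significance call, Pearson screening of protein
    abundance against a continuous per-animal covariate with fold and
    missingness gates, principal component analysis of the imputed
    matrix, and a synthetic-data generator emulating a six-group,
    three-replicate, two-sex design with intensity-dependent dropout so
    that every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
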
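Package: pairscan
Title: Pairwise Mixed-Type Feature Correlation Scanning and Redundancy
    Mapping for Multi-Domain Biomedical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing feature redundancy in multi-domain
    biomedical datasets that mix clinical tables, expression matrices and
    image-derived features. Cleans and merges longitudinal mixed-type
    tables, extracts tabular latent features from image stacks with a
    compact convolutional autoencoder, runs an all-vs-all association
    scan with automatic test dispatch (Pearson, Spearman, chi-squared,
    ANOVA, Kruskal-Wallis) driven by feature type and normality,
    controls the family-wise error rate by Bonferroni correction at the
    full comparison count, and summarises the retained pairs as
    per-feature correlate frequencies, feature-to-correlates mappings,
    representative-feature reductions and stratified subgroup
    revalidations. Includes a synthetic-data generator with known
    ground-truth correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
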
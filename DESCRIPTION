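Package: thagg
Title: Thermodynamic and Aggregation Fingerprinting of Immunoglobulin
    Light Chains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multiparametric biophysical
    characterisation of immunoglobulin light chains: position-specific
    scoring matrices (PSSMs) for protease cleavage-site prediction with a
    fragment-edge enrichment test, melting-temperature and
    aggregation-onset extraction from differential scanning fluorimetry
    and dynamic light scattering temperature scans, global two-state
    thermal/chemical unfolding fits with capillary bootstrap, sigmoidal
    thioflavin-T aggregation-kinetics fitting, and assembly of per-sample
    fingerprint tables with correlation and elastic-net analyses.  A
    synthetic-data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    minpack.lm,
    seqinr,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
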
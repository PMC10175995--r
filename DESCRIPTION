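Package: gcherit
Title: Heritability of the Directed Functional Connectome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the heritability of directed (effective) functional
    connectivity between brain networks. Per-node hemodynamic response
    functions are estimated blindly from resting-state BOLD-like series and
    removed by Wiener deconvolution; directed coupling between networks is
    then quantified by state-space Granger causality (pooled multi-session
    vector autoregression, innovations-form state space, reduced models via
    the discrete algebraic Riccati equation); finally each directed
    connection is treated as a quantitative trait and its additive-genetic
    and shared-environment variance shares (AE/ACE models) are estimated by
    maximum likelihood on kinship-structured family data, with
    boundary-corrected likelihood-ratio tests, Benjamini-Hochberg FDR
    control, and a kinship-aware discovery/replication split. A synthetic
    twin-cohort generator with known variance decomposition makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr
Config/testthat/edition: 3
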
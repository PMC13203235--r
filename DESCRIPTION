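Package: troughvar
Title: Intra-Individual Variability Analysis for Vancomycin Trough Monitoring
Version: 0.1.0
Authors@R:
    person("Trough", "Variability Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Patient-level analysis of intra-individual variability in
    therapeutic drug monitoring trough series, built for pre/post protocol
    audits of intravenous vancomycin. Computes per-patient variability
    metrics (coefficient of variation, swing index, mean absolute
    successive difference, range, zone changes, binary stability),
    classifies troughs into subtherapeutic/target/supratherapeutic zones,
    pools within-patient consecutive zone pairs into first-order Markov
    transition matrices per cohort, and compares cohorts with Mann-Whitney
    U tests, rank-biserial effect sizes, Fisher's exact test and Spearman
    correlations. A seeded synthetic cohort generator (lognormal AR(1)
    exposure model and zone-chain mode) makes the full pipeline testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
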
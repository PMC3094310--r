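Package: mixtoxsys
Title: Systems-Level Assessment of Binary Chemical Mixture Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrated assessment of binary chemical mixture
    toxicity in aquatic organisms: log-logistic dose-response fitting and ECx
    inversion, equitoxic fixed-ray mixture design in toxic units,
    Concentration-Addition and Independent-Action response-surface models with
    parametric deviation terms and a nested likelihood-ratio ladder for
    synergism/antagonism testing, first-order toxicokinetic elimination fits,
    a rule-based biomarker health status index, differential-expression
    overlap accounting and microarray/qPCR concordance scoring,
    efficiency-corrected relative expression with randomization testing, and
    hypergeometric GO-term enrichment with ancestor propagation and
    lowest-node summarisation. Seeded synthetic-data generators emulate every
    input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
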
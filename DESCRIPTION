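Package: hera
Title: Equity, Efficiency and Productivity of Health Resource Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the equity and efficiency of regional
    health care resource allocation from city-level panel data.  Implements
    weighted Lorenz curves and Gini coefficients, the Theil index with
    intra-/inter-regional decomposition and contribution rates, the health
    resource density index (HRDI), input-oriented CCR and BCC data
    envelopment analysis with two-phase slack maximisation and
    input/output adjustment targets, and adjacent-period Malmquist
    total-factor-productivity indices with the standard
    TFPC = TEC x TC and TEC = PTEC x SEC decompositions.  A seeded
    synthetic-panel generator with a known production technology provides
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
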
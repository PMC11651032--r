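Package: delphicodes
Title: Delphi Consensus Classification of ICD-9-CM Codes for
    Antimicrobial-Use Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for running and simulating a Delphi consensus procedure
    that classifies ICD-9-CM diagnosis and procedure codes as markers of
    hospital admissions with likely systemic antimicrobial therapy.
    Implements dual independent review with third-reviewer adjudication,
    9-point Likert voting rounds, the RAND/UCLA appropriateness agreement
    rule (median bands with the inter-percentile range adjusted for
    symmetry, IPRAS), a multi-round consensus engine, descriptive
    reporting (flow tallies and chapter breakdowns), and a seeded
    synthetic voting-panel generator for end-to-end testing without
    confidential panel data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
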
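Package: oncodda
Title: Digital Drug Assignment Decision Support for Precision Oncology
Version: 0.1.0
Authors@R:
    person("Oncodda", "Developers", email = "oncodda@example.org", role = c("aut", "cre"))
Description: An evidence-aggregation pipeline for molecular tumor board decision
    support. Filters somatic variant profiles with quality, population-frequency,
    ACMG-class and virtual-panel rules; scores parameterized evidence items into
    aggregated evidence levels (AEL) to classify driver alterations and rank
    registered compounds; flags actionability and drug resistance per case;
    re-tiers evidence on the ESCAT scale; virtually downsamples exome profiles to
    commercial gene panels to estimate panel performance; and runs cohort-level
    statistics (Mann-Whitney U, chi-square on AEL quartiles, driver landscape
    tallies). Ships a synthetic cohort and knowledgebase generator so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
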
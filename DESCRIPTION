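Package: tolaccea
Title: Cost-Effectiveness of Trial of Labour After Caesarean versus
    Elective Repeat Caesarean Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic cost-effectiveness model comparing a trial
    of labour after one previous caesarean delivery (TOLAC) with an elective
    repeat caesarean delivery (ERCD) for low-risk women over a six-week
    postpartum horizon. Provides validated parameter containers with a YAML
    configuration round-trip, bottom-up plus DRG bed-day micro-costing of
    delivery pathways and maternal complications, disutility-based QALY
    integration, deterministic decision-tree evaluation with ICER and
    dominance classification, probabilistic sensitivity analysis (normal
    costs and disutilities, beta branch probabilities) with
    cost-effectiveness plane and acceptability curve, an individual-level
    microsimulation oracle, and reproducible report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
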
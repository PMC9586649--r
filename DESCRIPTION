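Package: gcea
Title: Generalizability Theory and Cost-Effectiveness Analysis for
    Performance Assessments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates variance components from balanced multifacet rating
    data by the expected-mean-squares (ANOVA) method of generalizability
    theory, projects generalizability and dependability coefficients under
    alternative facet configurations (D studies), and couples those
    projections with a facet-linear cost model to compute incremental
    cost-effectiveness ratios and Monte-Carlo cost-effectiveness
    acceptability curves against willingness-to-pay thresholds.  Includes a
    balanced-design simulator for parameter-recovery studies and a
    reproducible four-step pipeline driven by a single configuration file,
    aimed at performance assessments such as multi-site OSCEs.
License: MIT + file LICENSE
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
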
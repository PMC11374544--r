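Package: platewaste
Title: Plate-Waste Accounting for School Meal Services
Version: 1.0.0
Authors@R:
    person("Plate Waste", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Quantifies school-canteen plate waste collected with the
    aggregate selective weighing method and translates it into nutritional
    losses, dietary-guideline compliance, embodied greenhouse-gas emissions
    (production, transport, disposal) and economic cost. Two procurement
    cases are compared with a normality-gated two-sample protocol
    (Lilliefors-corrected Kolmogorov-Smirnov screen, then Student's t or
    Mann-Whitney U). A synthetic-campaign generator with planted parameters
    makes every stage testable without access to raw campaign data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
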
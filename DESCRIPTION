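Package: oabcea
Title: Decision-Tree Cost-Effectiveness Model of Antimuscarinics for
    Overactive Bladder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort decision-tree model of 52 weeks of antimuscarinic
    therapy (fesoterodine, extended-release tolterodine, solifenacin) for
    overactive bladder with urgency incontinence. Loads and validates the
    published efficacy, persistence, resource-use, comorbidity, utility and
    cost inputs; propagates a unit cohort through week-4 dose titration, a
    week-12 responder gate and persistence-driven attrition under last
    observation carried forward; accrues quality-adjusted life years and
    per-patient euro costs under societal or payer perspectives; computes
    incremental cost-effectiveness ratios with dominance classification;
    and reproduces a full one-way (tornado) sensitivity grid. Includes a
    random parameter-set generator and an individual-level microsimulation
    oracle for property-based validation of the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
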
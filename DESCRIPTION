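Package: cvdcompare
Title: Comparing 10-Year Cardiovascular Disease Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coefficient-driven pipeline for comparing 10-year cardiovascular
    disease (CVD) risk prediction models on a participant-level cohort. Ships
    declarative coefficient configurations for six widely used risk equations
    (the Pooled Cohort Equations, a revised logistic-form PCE, the Framingham
    general CVD functions in lipid and BMI versions, and WHO-style laboratory
    and non-laboratory models), evaluates them through a shared risk engine,
    maps continuous risks to low/intermediate/high categories under uniform and
    model-specific threshold schemes, applies model-family statin-eligibility
    rules, and computes between-model concordance and discordance statistics
    (Spearman rank correlation, chi-square tests of independence, Wilson score
    intervals, high-risk risk-factor profiles). A seeded Gaussian-copula
    generator produces synthetic cohorts emulating the marginal risk-factor
    distributions of an urban Haitian adult population, so the full pipeline is
    testable without access to restricted participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
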
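Package: drstoch
Title: Stochasticity of Dietary-Restriction Lifespan Effects in Drosophila
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survival-analysis pipeline for quantifying how much of fly
    lifespan variation under dietary restriction (DR) is attributable to
    genotype, sex, cohort-level stochasticity, laboratory, and diet.
    Implements Kaplan-Meier estimation with Greenwood variance and
    Brookmeyer-Crowley median intervals, the two-group log-rank test, Cox
    proportional-hazards fitting by Newton-Raphson on the partial
    likelihood (Efron or Breslow ties), a Grambsch-Therneau style
    Schoenfeld-residual diagnostic, a likelihood-based covariate
    contribution statistic with Cox-Snell pseudo R-squared, per-stratum
    DR-vs-AL comparison grids with Bonferroni-corrected significance
    counting, and a Gompertz-mortality simulator of the two-lab factorial
    study design that generated the motivating data.
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
    survival,
    withr
Config/testthat/edition: 3
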
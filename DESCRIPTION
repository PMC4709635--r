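Package: discountmap
Title: Temporal Discounting Elicitation, Discount-Curve Fitting, and
    Voxel-Based Lesion-Symptom Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates and analyses adjusting-amount intertemporal-choice
    experiments. Provides generative choice agents and group-structured
    synthetic cohorts with lesion masks coupled to discounting behavior; the
    staircase titration task (Now, Not-now and control conditions) that
    converges on indifference points; hyperbolic and exponential
    discount-function fitting, area under the empirical discounting curve,
    and half-value delays; choice-consistency auditing; split-plot ANOVA
    with Fisher LSD post hocs and Kolmogorov-Smirnov normality screens; and
    voxel-based lesion-symptom mapping using the Brunner-Munzel rank test
    with false-discovery-rate control, cluster extent thresholding and
    statistical power maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
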
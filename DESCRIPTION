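Package: braintraj
Title: Growth and Degeneration Kinetics of Cross-Sectional Brain Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing cross-sectional trajectories of brain region
    size in mouse models of neurodevelopmental and neurodegenerative disease.
    Fits a piecewise exponential growth-degeneration model dA/dt = (G - D) A
    to group-mean area data, fits undergrowth-only and degeneration-only
    counterfactual variants, and computes atrophy percentages. Provides a
    summary-statistic inference battery (pooled and Welch two-sample t tests,
    one- and two-way ANOVA with Tukey HSD, slope comparison by linear
    regression) that runs from either raw animal-level records or published
    (mean, SEM, n) cells, histology morphometry operators (Purkinje-cell
    linear density, stain-positive area fraction, tile-based cell counts,
    puncta size statistics), and seeded generators for synthetic cohorts and
    microscopy images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
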
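Package: reefchrono
Title: Long-Term Trends and Homogenization of Caribbean Coral Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing multi-millennial change in Caribbean
    reef coral communities from heterogeneous presence/absence survey
    records. Harmonizes fossil, historical, and modern survey data into
    binned occurrence matrices, classifies corals into trait-based
    life-history guilds, models occurrence trends with binomial mixed
    models (country random intercept) plus marginal means and
    Tukey-adjusted contrasts, runs simulation-based residual diagnostics,
    and quantifies community homogenization with a country-equalized
    Jaccard dissimilarity bootstrap and permutation framework. Includes a
    synthetic survey generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    lme4,
    glmmTMB,
    vegan,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    mvtnorm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, StatisticalMethod, TimeCourse
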
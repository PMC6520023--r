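Package: phytosdm
Title: Ensemble Species Distribution Modelling of Phytoplankton Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to turn biased presence-only phytoplankton occurrence
    records into global monthly species-richness and species-turnover maps
    through ensemble species distribution models, together with the
    downstream macroecological analyses (metabolic-theory regressions of
    log richness on inverse thermal energy, and range-overlap null models).
    Includes record cleaning and monthly 1-degree gridding, target-group
    stratified pseudoabsence sampling, single-predictor skill ranking,
    randomised low-correlation predictor sets, GLM/GAM/random-forest member
    models evaluated by split-sample cross-validation and the true skill
    statistic, richness stacking with taxon balancing, Jaccard turnover
    partitioning, and a virtual-species simulator with known environmental
    niches so that every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    randomForest,
    geosphere,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
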
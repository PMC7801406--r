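Package: HydroCongruence
Title: Cross-Community Congruence Along Wetland Hydroperiod Gradients
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring congruence between site-by-taxon
    relative-abundance matrices of co-occurring horizontal communities
    (e.g. birds, aquatic macroinvertebrates, vascular plants) and between
    each community and a matrix of wetland hydroperiod indicators.
    Implements the Hellinger transformation, symmetric Procrustes
    superimposition with the m2 statistic and pseudo-R correlation, the
    PROTEST row-permutation significance test (with an exhaustive
    enumeration oracle for small n), a rarefaction sensitivity sweep for
    locating the sample-size plateau of the congruence estimate, a
    stratified balanced bootstrap for contrasting short- versus
    long-hydroperiod wetland groups, and a niche-based community
    simulator along a latent hydroperiod gradient with tunable direct
    cross-community coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Regression
RoxygenNote: 7.3.3
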
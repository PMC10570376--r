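Package: natphylo
Title: Phylogenetic Relatedness of Naturalized Alien and Native Regional Floras
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing Darwin's naturalization conundrum at the scale
    of regional floras. Computes cross-group mean pairwise phylogenetic
    distance (MPD) between naturalized alien and native species, compares it
    to null expectations under six alien source pools (DeltaMPD and SES.MPD
    with inverse-variance weights), grafts missing species onto genus or
    family backbones, derives climate principal components and a climatic
    envelope suitability stage for pool construction, and models how the
    distances vary with latitude, climate, and human landscape modification
    using weighted linear and mixed models, including a species-level
    complementary log-log naturalization model. A synthetic-world generator
    with known ground truth supports end-to-end validation and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phytools,
    lme4,
    car
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite
Config/testthat/edition: 3
biocViews: Phylogenetics, Software, StatisticalMethod
RoxygenNote: 7.3.3
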
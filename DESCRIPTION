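Package: skelevol
Title: Skeletal Volumetrics and Phylogenetic Macroevolution of Body Proportions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-body skeletal proportions across extant and
    fossil tetrapods: convex-hull body-segment volumetrics and whole-body convex
    hull volume (WBCHV) assembly, fossil-occurrence 'equal' time-scaling of
    cladograms, phylogenetic generalised least squares (linear and quadratic,
    with Pagel's lambda), phylogenetic ANCOVA, Mk-model fitting and stochastic
    character mapping of discrete ecological regimes, multi-regime Brownian
    motion and Ornstein-Uhlenbeck trait models with across-map summaries,
    Brownian-motion ancestral state reconstruction, and synthetic-data
    generators for validating every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
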
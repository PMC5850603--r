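Package: swarmevol
Title: Quantitative Analysis of Microbial Social-Evolution Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative arms of experimental-evolution studies of
    bacterial cooperation: exponential growth-rate estimation from plate-reader
    optical-density series using a fixed post-threshold window; actor-recipient
    competition statistics (benefit to actor and to recipient) from colony-forming-unit
    counts; a hierarchical-clustering clonal diversity score for phenotyped isolate
    panels; log-link generalized-linear-model normalization of LC-MS metabolite peak
    areas with family-wise-corrected ANOVA selection of changed metabolites, row
    standardization, and clustergram construction; and reporter-artifact filtering plus
    suppressor-locus classification of variant calls. A synthetic-data module generates
    every input with known ground truth so each stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
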
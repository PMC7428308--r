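Package: mossymap
Title: Quantification and Spatial Statistics of Cerebrocerebellar Mossy Fiber Terminal Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tract-tracing studies of disynaptic
    cerebrocerebellar pathways. Provides a cerebellar lobule atlas with
    MRT-based volumes, volume-normalized terminal density, laterality and
    symmetry measures, a two-threshold multimodal co-innervation
    classifier, aldolase-C (zebrin) parasagittal stripe assignment with
    cross-animal consistency checks, k-nearest-neighbor origin analysis,
    pairwise-distance comparisons, a three-dimensional Ripley's
    K-function with translation edge correction, and a Monte Carlo test
    against complete spatial randomness. A synthetic-study generator
    emulates multi-origin labeled point patterns and linked precerebellar
    cell counts so every stage is testable without experimental data.
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
    withr,
    yaml
Config/testthat/edition: 3
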
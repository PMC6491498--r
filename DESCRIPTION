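Package: resilnet
Title: Functional Network Resilience Analysis for Presymptomatic
    Genetic Frontotemporal Dementia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Wavelet-band functional connectivity and weighted graph
    analysis for studying resilience of the brain's functional network in
    presymptomatic genetic frontotemporal dementia. Provides a seeded
    synthetic cohort generator emulating a multi-site genetic FTD family
    study (gene-negative relatives, presymptomatic carriers and symptomatic
    patients, with per-family expected onset ages), a centroidal Voronoi
    parcellation generator, maximal-overlap discrete wavelet transform
    cross-correlation connectivity, density-thresholded weighted brain
    graphs normalized against degree-preserving null ensembles, hub
    identification, and a statistical layer of mixed-effects group
    contrasts with Satterthwaite degrees of freedom, piecewise breakpoint
    regression at expected symptom onset, hub-by-group interactions and
    per-group brain-volume and cognition associations, tied together by a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    lme4,
    lmerTest,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
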
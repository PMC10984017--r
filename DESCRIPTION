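Package: isoensemble
Title: Social-Rank, Lick-Microstructure and Neural-Ensemble Analysis for
    Isolation-Drinking Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for studies linking social dominance rank and
    social isolation to alcohol drinking and to amygdala-cortical neural
    activity. Provides tube-test rank scoring, lick-microstructure bout
    segmentation and condition contrasts, pose-keypoint social-interaction
    detection, peri-event calcium trace alignment with baseline Z-scoring
    and responsive-neuron classification, hierarchical functional
    clustering with group-enrichment tests, pseudo-simultaneous population
    SVM decoding with shuffle controls, and cross-session ensemble-overlap
    statistics. Includes a seeded synthetic-cohort generator with planted
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    cluster,
    e1071,
    emmeans,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'behavior.R'
    'utils.R'
    'decoding.R'
    'ensembles.R'
    'io.R'
    'isoensemble-package.R'
    'neural.R'
    'pose.R'
    'synth.R'
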
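Package: deviantcoding
Title: Layer-Resolved Analysis of Sensory Deviant Encoding in Barrel Cortex
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for oddball (deviant) encoding in mouse primary
    somatosensory cortex recordings. Implements per-neuron change coefficients
    for amplitude deviants in repeated whisker-deflection trains, surrogate-null
    population broadening tests (interquartile range and Shannon entropy with
    bootstrap inference), a GLM classifier for phasically stimulus-driven units,
    a penalized Poisson GLM with a difference-operator regularizer over the
    adaptation profile, a percentile-baseline dF/F calcium-imaging chain with
    neuropil-annulus light-artifact correction, and psychometric analysis of a
    go/no-go detection task. A synthetic-data generator plants known encoding
    structure (layer-specific change coefficients, optogenetic ensemble
    shuffling, GCaMP6s-kernel transients, a deviant-benefit observer) so every
    stage is testable against ground truth.
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
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-internal.R'
    'stimulus.R'
    'io.R'
    'unit-processing.R'
    'sim-spikes.R'
    'sim-calcium.R'
    'sim-behavior.R'
    'driven-classifier.R'
    'change-coding.R'
    'neuron-glm.R'
    'calcium.R'
    'behavior.R'
    'cli.R'
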
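Package: placeseq
Title: Place-Cell Population Sequence Analysis on the Circular Track
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for hippocampal CA1 tetrode recordings from
    rats running unidirectionally on a circular track. Builds
    occupancy-normalized firing-rate maps and place fields, quantifies theta
    phase precession by circular-linear regression, decodes position from
    population spike counts with a Poisson Bayesian decoder, detects and
    scores theta sequences against a circular-shuffle null, detects and
    classifies rest-period replay events, and characterizes replay-associated
    LFP power (sharp wave-ripples and slow gamma). Includes a synthetic
    session generator with known ground truth (place tuning, phase
    precession, scripted replay trajectories, ripple bursts) so every stage
    of the pipeline can be exercised and validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
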
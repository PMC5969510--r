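Package: ccDFS
Title: Dynamic Force Spectroscopy Analysis of Coiled-Coil Rupture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of AFM-based single-molecule force
    spectroscopy (SMFS) experiments on dimeric coiled coils loaded in the
    shear geometry. Provides a stochastic simulator of force-extension
    retract curves (worm-like-chain PEG spacers in series with a soft
    cantilever, single-bond rupture following Bell kinetics under the
    realized loading schedule, additive Gaussian force noise) and the
    complete inference chain from raw curves to force-free dissociation
    rate and potential width: baseline correction, rupture detection,
    worm-like-chain fitting with contour-length and goodness filters,
    per-curve loading rates from the slope at rupture, per-speed
    rupture-force and loading-rate histograms with Gaussian most-probable
    values, and Bell-Evans regression with replicate aggregation. A
    plateau-force branch supports comparison with steered molecular
    dynamics style traces via the k_L speed-to-loading-rate conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'core-model.R'
    'constructs.R'
    'simulate.R'
    'curve-analysis.R'
    'dfs-inference.R'
    'plateau.R'
    'io.R'
    'pipeline.R'
    'cli.R'
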
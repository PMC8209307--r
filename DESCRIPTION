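Package: dendiam
Title: Predicting Dendritic Diameters from Neuronal Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to predict dendritic diameters of neuronal
    reconstructions from diameter-independent morphological features.
    Reads and writes SWC morphology files, computes per-node
    morphometric features (parent diameter, branch order, terminal
    degree, path length to soma, longest path to a terminal tip, total
    downstream arbor length), classifies dendritic nodes as initial,
    branching-child or continuing, fits node-class-specific linear
    diameter models by ordinary least squares through the origin with
    adjusted-R-squared stepwise feature selection, and applies fitted
    or packaged model sets to a morphology by soma-outward traversal.
    A passive cable compartmental simulator extracts membrane time
    constants, steady-state deflections and synaptic peaks so that
    morphologies with predicted diameters can be compared electrically
    against the originals.  A synthetic morphology generator with
    ground-truth diameter rules makes the whole pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
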
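Package: meglayer
Title: Multi-Layer Amplitude-Envelope Connectivity for MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating electrophysiological functional connectivity
    as band-limited amplitude-envelope correlation, within and between
    frequency bands, and assembling the results into a multi-layer
    super-adjacency matrix. Includes scalar LCMV beamforming with Gaussian
    regional aggregation, pairwise leakage orthogonalization,
    magnetomyogram artifact regression, permutation statistics for
    task-induced connectivity change, a diagnosis-versus-severity
    tile-correlation test with dual permutation nulls, and a synthetic-data
    generator with planted envelope couplings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
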
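Package: cortexwaves
Title: Traveling-Wave Analysis of Delay-Coupled Oscillators on Cortical Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates delay-coupled Kuramoto phase oscillators on a spatially
    embedded cortical connectome with intermittently resampled intrinsic
    frequencies, and quantifies the resulting traveling waves: equal-area
    surface mapping, circular-linear phase-gradient estimation, propagation
    speed and direction, source-sink analysis of local radial waves,
    phase-based network segmentation (Cohen's d with permutation inference),
    unidirectional communication indices, and frequency-to-phase sequencing
    statistics. Includes a synthetic-connectome generator emulating the
    statistical structure of diffusion-MRI connectomes (distance-decaying
    weights, hub heterogeneity, conduction delays, contiguous network
    parcels) plus pipeline and parameter-sweep drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
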
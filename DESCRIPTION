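Package: neuritescope
Title: Quantification of Mitochondrial Transport, Neurite Morphometry and
    MEA Functional Connectivity in Engineered Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrated image analysis and extracellular electrophysiology
    post-processing for multi-nodal neural networks grown in microfluidic
    devices. Detects fluorescently labelled mitochondria inside axon
    tunnels, builds kymographs and measures transport speed, direction and
    motile ratios; counts neuritic boutons as skeleton endpoints and
    quantifies pre/postsynaptic marker co-occurrence; band-pass filters
    microelectrode array recordings, detects spikes by a median-anchored
    threshold and estimates lagged Pearson functional connectivity with
    activity and significance filters. A synthetic-data generator with
    full ground truth makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    signal,
    stats,
    tiff,
    utils,
    yaml,
    zoo
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
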
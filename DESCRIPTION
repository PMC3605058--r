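Package: avkit
Title: Neuronal Avalanche Analysis Across Vigilance States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize neuronal avalanches in multichannel
    electrophysiological recordings across vigilance states. Extracts
    rate-matched binary events from local field potential (LFP) signals via
    deflection-lobe areas, bins events in units of the mean inter-event
    interval, computes avalanche sizes, durations and branching parameters,
    fits discrete heavy-tailed distributions (power law with and without
    exponential cutoff, exponential, Poisson, lognormal, stretched
    exponential) by maximum likelihood with bootstrap goodness of fit,
    performs avalanche shape collapse, and compares avalanche measures
    between states with cluster-based permutation statistics. Includes a
    tunable 3D Bak-Tang-Wiesenfeld sandpile model with spatial subsampling
    and virtual-LFP electrodes, plus generators for synthetic event rasters
    and whole-night multichannel recordings with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
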
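Package: qdyefinder
Title: Colour-Based Identification of Neurites in Super-Multicolour
    Labelled Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies neurites belonging to individual neurons in
    densely multicolour-labelled (up to 7 fluorescent proteins) brain
    tissue from colour information alone.  Provides detector linearity
    correction and reference-based linear spectral unmixing of
    multichannel volumes, extraction of per-channel colour vectors from
    traced neurite fragments (SWC format) with a staged quality-control
    pipeline, the dCrawler threshold-distance clustering algorithm,
    evaluation against ground-truth neuron labels (per-neuron F1 and
    percent reconstructed), stochastic-labelling simulations of colour
    discriminability and uniqueness under Poisson copy-number models,
    and a phantom generator producing synthetic labelled volumes with
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    mclust,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
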
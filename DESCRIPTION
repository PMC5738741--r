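Package: synapsedetect
Title: Automated Detection of Axonal Boutons, Dendritic Spines and
    Synapses in Two-Photon Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects presynaptic axonal boutons, postsynaptic dendritic
    spines, and putative bouton-spine synapses in dual-channel in vivo
    two-photon image stacks. Boutons are enhanced with a Hessian-based
    blob detector built on a Gaussian-surface intensity model, dendrites
    with a Hessian-based ridge detector built on a Gaussian cross-section
    model. Dendrite masks are reduced to one-pixel skeletons with a
    two-subiteration parallel thinning algorithm; spine candidates are
    read off branch points and pruned spurs and screened against
    axon-like structures. Boutons and spines are paired into per-layer
    synapses by lateral distance and linked across layers by mutual
    nearest neighbours to count three-dimensional structures. A synthetic
    stack generator with exact ground truth supports end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
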
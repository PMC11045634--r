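Package: metastasim
Title: Hybrid Multiscale Simulation of Tumour Invasion and Multi-Organ Metastasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genuinely hybrid, multiscale simulator of cancer invasion and
    metastasis. Epithelial-like cancer cells, cancer-associated fibroblasts,
    TGF-beta, matrix metalloproteinases and the extracellular matrix evolve as
    coupled density fields with degenerate porous-medium diffusion, haptotaxis
    and logistic reaction kinetics, while mesenchymal-like cancer cells are
    tracked as solitary stochastic agents driven by saturated haptotactic drift
    and compound-Poisson jump noise. Mass-conservative operators convert
    between the density and agent phases, TGF-beta-gated Poisson processes
    switch phenotypes (EMT/MET), and a multi-organ circulatory network carries
    circulating tumour cells between organs. Ships four ready-made numerical
    experiments (haptotaxis flow, cancer-cell islands, merging microtumours,
    multi-organ metastasis) at configurable resolution.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
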
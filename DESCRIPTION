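Package: itermask
Title: Iterative-Masking Sequence Generation and Statistical Comparison of Protein MSAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates protein sequences from masked-sequence models by an
    iterative masking procedure over multiple sequence alignments (MSAs), and
    provides the statistical machinery to compare natural and synthetic MSAs:
    Potts (direct coupling analysis) models with exact enumeration,
    Metropolis-Hastings sampling at tunable temperature, statistical-energy
    scoring and a minimal Boltzmann-machine fitter; low- and higher-order MSA
    statistics (connected correlations, mutual information, co-information,
    r20 curves, effective depth); sequence-space analyses (Hamming distances,
    closest-natural lookup, one-hot PCA, nearest-neighbour score transfer,
    additive deep-mutational-scanning scores); and phylogenetic spectral
    analysis via neighbour-joining trees and modified graph Laplacian
    eigenvalue densities. An exact Potts-conditional oracle implements the
    masked-sequence-model contract so the whole pipeline is testable at desk
    scale without pretrained weights.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
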
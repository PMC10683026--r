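Package: CoevCV
Title: Coevolution-Guided Collective Variables and Free-Energy Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for coevolution-driven exploration of protein
    conformational states. Fits a Potts model to a multiple sequence
    alignment by pseudo-likelihood maximisation (direct coupling
    analysis), scores residue-residue couplings with an average product
    correction, and overlays them with a structure-derived contact map to
    find high-scoring pairs that are distant in the reference structure.
    Those pairs seed steering coordinates for enhanced-sampling molecular
    dynamics; trajectories from exploration runs are distilled into a
    pair of collective variables with a linear maximum-margin classifier.
    Downstream analysis covers histogram-based free-energy surfaces,
    reweighted projections onto arbitrary observables, basin detection
    and Boltzmann population estimates, convergence diagnostics for
    multi-walker adaptive-bias sampling, and residue-level energetic
    coupling networks analysed by shortest paths and betweenness
    centrality. Synthetic-data generators with known ground truth
    (Gibbs-sampled alignments, toy structures, Metropolis-sampled
    two-state trajectories) make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Biostrings,
    bio3d,
    e1071,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Alignment, Network
RoxygenNote: 7.3.3
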
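Package: pepForge
Title: Fusion-Driven Classification and Conditional Diffusion Generation of Anticancer Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for anticancer-peptide (ACP) modelling built around two
    components that share one fused feature space. The classifier couples
    protein-language-style sequence embeddings with a 430-dimensional
    physicochemical descriptor block, compresses the fusion through a
    multiscale channel/spatial attention stage, and trains a noise-conditioned
    multiclass network under SMOTE rebalancing and class-weighted
    cross-entropy. The generator is a conditional denoising-diffusion model
    over descriptor space with bitemporal and temporal-feature-attention
    fusion modules, fast ODE-style sampling, and a Markov decoder emitting
    8-50 residue candidate peptides organised by cancer type. Downstream
    screening provides Smith-Waterman novelty scans, motif summaries and
    helical-wheel projections, plus the physicochemical profiling (net charge,
    isoelectric point, hydrophobic moment, instability index) used to vet
    candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
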
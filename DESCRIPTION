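Package: scPotency
Title: Absolute Developmental Potency Prediction from Single-Cell RNA-Seq
    with Gene-Set Binary Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts absolute developmental potency of single cells from
    scRNA-seq expression matrices using an interpretable ensemble of gene-set
    binary networks (GSBNs). Each of six ordered potency categories
    (differentiated through totipotent) is modelled by a module whose hidden
    units are literal gene sets, scored per cell by a rank-based (UCell-style)
    enrichment score and an expression-bin background-subtracted module score.
    Softmax category likelihoods yield a continuous potency score in [0,1]
    that is refined by Markov diffusion, category-preserving binning, and
    adaptive k-nearest-neighbour smoothing. Includes training with
    straight-through-estimator backpropagation, hierarchy-balanced loss
    weights and early stopping; feature-importance interpretation; weighted
    Kendall tau / mean multiclass F1 / MAE evaluation metrics; and a
    potency-structured synthetic-data generator with label-noise,
    downsampling and rarity-titration perturbations for robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, GeneExpression, Classification
RoxygenNote: 7.3.3
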
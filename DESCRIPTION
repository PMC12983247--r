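Package: menet
Title: Mixed-Effect Deep Neural Networks for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction of quantitative traits with a mixed-effect
    deep neural network. A phenotype-aware triplet-contrastive encoder
    (RepGeno) embeds trait-specific genetic relatedness as the random-effect
    branch, while a residual one-dimensional convolutional network (VE)
    embeds the cumulative, possibly nonlinear, effect of genomic variants as
    the fixed-effect branch. The two embeddings interact through
    cross-information feature fusion and a fully connected prediction head.
    Includes genotype quality control (minor-allele-frequency filtering and
    sliding-window linkage-disequilibrium pruning), a quantitative-trait
    simulator with epistasis, family structure and genotype-by-environment
    effects, two-stage training with AdamW and plateau learning-rate
    scheduling, cross-environment transfer learning that fine-tunes only the
    fusion correction network and prediction head, and integrated-gradients
    attribution of the two branches' contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'GenotypeData-class.R'
    'genotype-io.R'
    'interpret.R'
    'repgeno.R'
    'menet-model.R'
    'metrics.R'
    'nn-core.R'
    'pipeline.R'
    'simulate.R'
    'trainer.R'
    'utils.R'
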
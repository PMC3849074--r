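Package: metaRSVM
Title: Alignment-Free Supervised Classification of Metagenomes with
    k-Tuple Signatures and Recursive SVM
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised classification of metagenome samples directly from
    unassembled short reads. Features are k-tuple (k-mer) occurrence
    frequencies counted from the reads, normalised for sequencing depth and
    standardised per feature. Classification and feature selection are
    performed jointly by recursive SVM (R-SVM): a linear support vector
    machine is trained, features are ranked by their class-mean difference
    weighted by the SVM weight, and the top-ranked features are retained
    down a descending ladder of feature-set sizes. Performance is assessed
    by leave-one-out cross-validation with feature selection and
    standardisation refit inside every fold, and significance by a
    label-permutation test. A seed-insertion genome and read simulator is
    included for generating fully characterised two-class benchmark data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    SummarizedExperiment,
    S4Vectors,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Classification, Metagenomics, Sequencing, FeatureExtraction,
    SupportVectorMachine
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'benchmark.R'
    'evaluation.R'
    'io.R'
    'kmer.R'
    'metaRSVM-package.R'
    'permutation.R'
    'rsvm.R'
    'simulate.R'
    'utils.R'
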
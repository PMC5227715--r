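Package: ramESVM
Title: Ensemble Support Vector Machines for N6-Methyladenosine Site Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects N6-methyladenosine (m6A) sites in 51-nt RNA windows
    centered on an adenosine by majority voting over three heterogeneous
    support vector machine base classifiers: pseudo dinucleotide composition
    (PseDNC) built from dinucleotide thermodynamic properties, Boolean
    class-discriminative substring (motif) features, and a gapped k-mer
    string kernel. Includes full training, prediction, jackknife and k-fold
    evaluation machinery, a synthetic benchmark generator with a plantable
    consensus motif, and the closed-form analysis of when majority voting
    beats its best single classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    Matrix,
    e1071,
    SparseM,
    kernlab,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Classification, Epigenetics, FeatureExtraction,
    SupportVectorMachine, Transcriptomics
RoxygenNote: 7.3.3
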
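Package: tetraPPI
Title: Chain Interaction and Interface Residue-Pair Prediction for
    Tetramer Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage prediction of interactions inside four-chain
    (tetramer) protein complexes. Stage one summarises each chain as a
    20 x 24 matrix of same-type amino-acid position and geometry
    change-sequence statistics, forms a standardised absolute-difference
    feature map for each of the six chain pairs, and classifies chain-pair
    interaction with a small convolutional neural network. Stage two
    describes every residue by 460 sequence and structure descriptors
    (circular k-interval product and k-average cumulation factors over
    physicochemical scales; distance-ranked neighbour product, cumulation
    and exponential-weight factors over geometric properties), scores
    920-dimensional residue-pair vectors with an ensemble of
    under-sampled radial-basis support vector machines, and ranks
    candidate interface residue pairs per chain pair. Includes PDB and
    property-table readers, distance-based contact labelling, top-t
    interface evaluation metrics (PT vector, NPIRP vector and norms,
    Accuracy4t), and a synthetic tetramer generator for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'physchem.R'
    'structures-io.R'
    'chain-features.R'
    'cnn.R'
    'residue-features.R'
    'svm-ensemble.R'
    'evaluation.R'
    'simulate.R'
    'tetraPPI-package.R'
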
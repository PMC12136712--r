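Package: phagekit
Title: Characterization Pipeline for Lytic Bacteriophages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational characterization of lytic bacteriophages from
    sequence, structure and plate-assay data. Implements physicochemical
    featurization of tail proteins (431 descriptors: amino-acid and
    dipeptide composition plus ProtParam-style scalars), random-forest
    family classification with stratified cross-validation, pan-genome
    core/accessory/unique partitioning with greedy centroid clustering,
    fragment-based average nucleotide identity (OrthoANI scheme), UPGMA
    trees, efficiency-of-plating and one-step growth-curve statistics,
    protein-protein interface-region extraction at a distance cutoff, and
    alignment conservation / sequence-logo profiling. Seeded synthetic-data
    generators allow every stage to run and be validated without network
    access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    bio3d,
    randomForest,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
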
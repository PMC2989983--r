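Package: glycorbf
Title: O-Linked Glycosylation Site Prediction with RBF Networks and
    Significant Amino Acid Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts O-linked glycosylated serine and threonine residues
    from protein sequence. Candidate sites are encoded as fixed-length
    sequence windows using normalized BLOSUM62 rows plus binary indicators
    of significant amino acid pairs (SAAPs) discovered by F-score feature
    selection, and classified with a Gaussian radial basis function
    network whose centers are the training instances and whose output
    weights are solved as a linear system. Separate models are built for
    transmembrane and non-transmembrane proteins, and membrane topology
    annotations can be used to veto predictions falling inside
    transmembrane segments. Includes a synthetic glycoprotein data
    generator with controllable motif signal, sequence-level k-fold
    cross-validation, homology reduction of redundant fragments, and
    AAindex-style physicochemical property screening.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
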
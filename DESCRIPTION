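Package: phylodist
Title: Fast Distance-Based Phylogenetics: Sequence Distances and
    Neighbor-Joining Tree Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A composable toolchain for distance-based phylogenetics.
    Estimates pairwise evolutionary distances from DNA alignments
    (p-distance, Jukes-Cantor, Kimura two-parameter, Tamura-Nei 1993)
    with optional fractional counting over IUPAC ambiguity codes, and
    from protein alignments (Jukes-Cantor and Kimura corrections, plus
    pairwise maximum-likelihood and posterior-expected distances under
    the empirical WAG, JTT, Dayhoff, VT and LG substitution models).
    Reconstructs unrooted phylogenies from distance matrices with
    canonical Neighbor-Joining, Fast Neighbor-Joining (visibility set,
    quadratic work) and BioNJ.  Supports FASTA, PHYLIP (strict and
    relaxed, sequential and interleaved), an XML dialect, Newick, and a
    compact streaming binary upper-triangular distance-matrix format;
    column-resampling bootstrap with seeded, per-replicate reproducible
    substreams; and a synthetic-data generator (random trees, additive
    matrices, sequences evolved under the supported models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    withr
Config/testthat/edition: 3
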
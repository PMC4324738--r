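Package: mitomir
Title: Discovery and Target Annotation of Mitochondrial microRNA Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for predicting candidate precursor and
    mature microRNA in small (mitochondrial) genomes and for annotating their
    targets. Finds inverted repeats with an einverted-style banded dynamic
    program, folds candidate windows into minimum-free-energy hairpins with a
    nearest-neighbor energy model, filters real from pseudo pre-miRNA hairpins
    using triplet structure-sequence features and a dinucleotide-preserving
    shuffle P-value, computes physicochemical properties of mature sequences,
    scans for target sites with a 5'-weighted complementarity score followed by
    an intermolecular duplex free-energy filter, performs BLAT-style
    seed-and-extend homology search across genomes, and intersects and
    annotates multi-tool target-site lists against gene and disease maps.
    Includes a seeded synthetic-fixture generator (random genomes with planted
    hairpins and target sites) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
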
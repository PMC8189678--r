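Package: rnaforge
Title: Multi-Scale RNA Structure and Homology Dataset Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multi-scale per-nucleotide datasets for RNA 3D chains by
    combining geometric annotation of atomic coordinates with homology
    information summarized from multiple sequence alignments. Parses and
    normalizes RNA chains from mmCIF files (renumbering, ligand removal,
    modified-base folding), computes backbone torsion angles, glycosidic
    and ribose endocyclic torsions, eta/theta pseudotorsion systems and
    sugar-pucker pseudorotation labels, summarizes Stockholm or aligned
    FASTA alignments into position-specific scoring matrices, and merges
    the two per-position information sources with a gap-aware remapping
    algorithm. Includes chain selection through redundancy equivalence
    classes, a single-file relational dataset store with CSV export and
    date/resolution filtering, sequence identity matrices with Ward
    clustering, periodic kernel density estimation of pseudotorsion
    couples, and a synthetic-fixture generator producing idealized helices
    with exact pseudorotation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
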
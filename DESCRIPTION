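Package: connexo
Title: Connexin Gene-Family Curation, Orthology Harmonization and Ohnolog Detection
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained pipeline for vertebrate gene-family evolution
    analyses of the connexin (gap-junction protein) family. Curates candidate
    coding sequences by the conserved extracellular-loop cysteine signatures
    and transmembrane hydropathy, builds cysteine-anchored conserved-domain
    alignments, computes pairwise-deletion evolutionary distances under
    p-distance, Poisson+Gamma and JTT+Gamma models, infers Neighbor-Joining
    trees with bootstrap clade support, harmonizes orthogroup names by the
    three-order incremental tree-building protocol with consistency flags,
    applies cyclostome-style naming rules for lineage genes without clear
    orthology, detects within-species duplicate pairs and classifies them as
    whole-genome-duplication ohnologs versus tandem duplicates, and validates
    everything against a bundled birth-death gene-family simulator with
    whole-genome duplications of different ages and full truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Phylogenetics, Alignment, SequenceMatching, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
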
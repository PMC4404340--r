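Package: mitopop
Title: Mitochondrial Barcode Phylogeography: Haplotypes, Diversity, AMOVA and Species Delimitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for single-locus mitochondrial barcode
    phylogeography (e.g. cox1 surveys of insect populations): haplotype
    collapsing from aligned sequences, haplotype and nucleotide diversity,
    Tajima's D and Fu's Fs neutrality tests, Kimura two-parameter distances
    and neighbor-joining trees, distance-based AMOVA with permutation
    Phi-statistics and pairwise FST, great-circle geographic distances and
    Mantel isolation-by-distance tests, Automatic Barcode Gap Discovery
    species delimitation, median-joining haplotype networks, and a synthetic
    sequence generator (star expansion and Kingman coalescent) so every
    stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
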
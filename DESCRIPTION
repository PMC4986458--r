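Package: homeolink
Title: Linkage-Map-Anchored Subgenome Phylogenetics for Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Disentangles the subgenomes of allopolyploids from targeted
    sequence capture of an F1 cross. Calls single-subgenome segregating
    SNPs from multi-sample pileups with depth, allele-frequency and
    Mendelian-segregation filters, groups them into linkage groups by
    two-point LOD, anchors phylogenetically informative variants to
    linkage groups through shared sequence reads, classifies
    phylogenetic support versus introgression-like and outgroup
    homoplasy to detect interhomeolog introgression clusters, and
    detects and tests interchromosomal rearrangements with a
    permutation null. Includes a synthetic allo-octoploid cross
    simulator with planted introgression tracts and transpositions so
    the whole pipeline can be exercised and validated at desk scale,
    plus helpers for scaffold ordering into pseudochromosomes and
    cross-genus synteny-stretch counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    ape,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn
Config/testthat/edition: 3
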
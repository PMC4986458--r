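#' Published region-count table for the octoploid strawberry crosses
#'
#' Per-subgenome, per-chromosome counts of 1-kb regions showing
#' phylogenetic support, clustered and isolated introgression-like
#' homoplasy, outgroup homoplasy and mixed support/homoplasy for the two
#' wild octoploid strawberry (Fragaria) mapping crosses, as published for
#' the targeted-capture linkage-map dataset; distributed with the package
#' for reanalysis. Layout matches [make_table1()] (chromosome columns
#' `I`..`VII` plus `total`), with additional `All` rows for informative
#' markers, total markers and percent missing data.
#'
#' @return data.frame.
#' @export
load_fragaria_region_counts <- function() {
  utils::read.table(
    system.file("extdata", "fragaria_region_counts.tsv",
                package = "homeolink"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    check.names = FALSE)
}

#' Published introgression clusters for the octoploid strawberry crosses
#'
#' The 48 introgression clusters (reference chromosome, first and last
#' marker site, subgenome, contributing 1-kb region count and parental
#' maps) published for the octoploid strawberry targeted-capture dataset;
#' distributed with the package for reanalysis of cluster geometry.
#'
#' @return data.frame with columns `chrom`, `start`, `end`, `subgenome`,
#'   `regions`, `maps`.
#' @export
load_fragaria_clusters <- function() {
  utils::read.table(
    system.file("extdata", "fragaria_introgression_clusters.tsv",
                package = "homeolink"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
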
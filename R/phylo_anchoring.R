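#' Extract phylogenetic markers anchored to linkage groups by shared reads
#'
#' An LG SNP's minor allele tags the one homeolog it segregates on. Reads
#' that cover the LG SNP and carry the minor allele therefore come from
#' that homeolog, and any other variant site on those reads can be
#' attributed to the LG SNP's linkage group. For each LG SNP and each
#' variant site within a read length, the base reported for the linkage
#' group is the strict-majority consensus of the qualifying reads covering
#' the site; an exact tie yields no marker. LG SNP positions themselves are
#' never emitted as markers (the minor variant is private to one subgenome
#' and carries no interhomeolog signal).
#'
#' @param reads data.frame of gapless alignments with columns `sample`,
#'   `chrom`, `start` (1-based leftmost reference position) and `seq`
#'   (aligned bases, one per consecutive reference position).
#' @param lg_snps data.frame with columns `chrom`, `pos`, `minor_allele`,
#'   `group` (linkage-group id) and optionally `samples` (list-column of
#'   sample names whose reads may be used; default all).
#' @param variant_sites data.frame with columns `chrom`, `pos`: candidate
#'   sites segregating among linkage groups and/or diploid taxa.
#' @param read_length maximum anchor distance in bp (default 100).
#' @param min_support minimum number of qualifying reads covering a site
#'   (default 1).
#' @return data.frame with columns `chrom`, `pos`, `group`, `base`,
#'   `support`, `distance` (bp to the anchor LG SNP).
#' @export
extract_anchored_markers <- function(reads, lg_snps, variant_sites,
                                     read_length = 100, min_support = 1) {
  lg_key <- paste(lg_snps$chrom, lg_snps$pos)
  reads$end <- reads$start + nchar(reads$seq) - 1L
  reads_by_chrom <- split(reads, reads$chrom)
  out <- vector("list", nrow(lg_snps))
  for (i in seq_len(nrow(lg_snps))) {
    snp <- lg_snps[i, ]
    rc <- reads_by_chrom[[snp$chrom]]
    if (is.null(rc)) next
    r <- rc[rc$start <= snp$pos & rc$end >= snp$pos, , drop = FALSE]
    if ("samples" %in% names(lg_snps) && !is.null(snp$samples[[1L]])) {
      r <- r[r$sample %in% snp$samples[[1L]], , drop = FALSE]
    }
    if (nrow(r) == 0L) next
    base_at <- substr(r$seq, snp$pos - r$start + 1L, snp$pos - r$start + 1L)
    r <- r[toupper(base_at) == snp$minor_allele, , drop = FALSE]
    if (nrow(r) == 0L) next
    vs <- variant_sites[variant_sites$chrom == snp$chrom &
                          abs(variant_sites$pos - snp$pos) < read_length &
                          !(paste(variant_sites$chrom, variant_sites$pos)
                            %in% lg_key), , drop = FALSE]
    if (nrow(vs) == 0L) next
    rows <- vector("list", nrow(vs))
    for (j in seq_len(nrow(vs))) {
      p <- vs$pos[j]
      cov <- r$start <= p & r$end >= p
      if (sum(cov) < min_support) next
      bases <- toupper(substr(r$seq[cov], p - r$start[cov] + 1L,
                              p - r$start[cov] + 1L))
      bases <- bases[bases %in% c("A", "C", "G", "T")]
      if (length(bases) < min_support) next
      tab <- table(bases)
      top <- names(tab)[tab == max(tab)]
      if (length(top) != 1L) next      # exact tie: missing
      rows[[j]] <- data.frame(chrom = snp$chrom, pos = p,
                              group = snp$group, base = top,
                              support = as.integer(max(tab)),
                              distance = abs(p - snp$pos),
                              stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), pos = integer(0),
                      group = character(0), base = character(0),
                      support = integer(0), distance = integer(0))
  }
  # one consensus per (group, site): merge across anchors by support-weighted
  # majority; conflicting equal-support bases drop to missing
  if (nrow(res) > 1L) {
    key <- paste(res$group, res$chrom, res$pos)
    if (anyDuplicated(key)) {
      parts <- split(res, key)
      res <- do.call(rbind, lapply(parts, function(d) {
        w <- tapply(d$support, d$base, sum)
        top <- names(w)[w == max(w)]
        if (length(top) != 1L) return(NULL)
        d <- d[d$base == top, , drop = FALSE][1L, ]
        d$support <- as.integer(max(w))
        d
      }))
      rownames(res) <- NULL
    }
  }
  res
}

#' Assemble per-chromosome taxon-by-site matrices
#'
#' Rows are linkage groups (both parents, both species) plus diploid taxa
#' and the outgroup; columns are variant sites. Cells hold the anchored
#' consensus base for linkage groups and the called base for diploid taxa,
#' `NA` where no qualifying read or call exists. Sites with fewer than one
#' non-missing cell are dropped, and each chromosome yields its own matrix.
#'
#' @param markers anchored markers from [extract_anchored_markers()].
#' @param taxon_calls data.frame of diploid/outgroup calls with columns
#'   `taxon`, `chrom`, `pos`, `base`.
#' @param groups optional character vector fixing the row order of linkage
#'   groups; defaults to sorted unique groups present.
#' @return named list of character matrices, one per chromosome; column
#'   names are site positions.
#' @export
build_taxon_matrix <- function(markers, taxon_calls, groups = NULL) {
  chroms <- sort(unique(c(markers$chrom, taxon_calls$chrom)))
  if (is.null(groups)) groups <- sort(unique(markers$group))
  taxa <- unique(taxon_calls$taxon)
  out <- list()
  for (ch in chroms) {
    mk <- markers[markers$chrom == ch, , drop = FALSE]
    tc <- taxon_calls[taxon_calls$chrom == ch, , drop = FALSE]
    sites <- sort(unique(c(mk$pos, tc$pos)))
    if (length(sites) == 0L) next
    mat <- matrix(NA_character_, nrow = length(groups) + length(taxa),
                  ncol = length(sites),
                  dimnames = list(c(as.character(groups), taxa),
                                  as.character(sites)))
    if (nrow(mk) > 0L) {
      mat[cbind(match(as.character(mk$group), rownames(mat)),
                match(mk$pos, sites))] <- mk$base
    }
    if (nrow(tc) > 0L) {
      mat[cbind(match(tc$taxon, rownames(mat)),
                match(tc$pos, sites))] <- tc$base
    }
    keep <- colSums(!is.na(mat)) >= 1L
    mat <- mat[, keep, drop = FALSE]
    if (ncol(mat) > 0L) out[[ch]] <- mat
  }
  out
}

#' Pairwise p-distances with pairwise deletion
#'
#' Proportion of differing sites among sites non-missing in both taxa.
#' Pairs with zero shared sites get the maximum observed distance (flagged
#' in the `no_overlap` attribute) so tree building can proceed.
#'
#' @param mat character matrix taxa x sites with `NA` for missing.
#' @return dist-like symmetric matrix with attribute `no_overlap`
#'   (logical matrix marking imputed pairs).
#' @export
p_distance_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  shared <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      shared[i, j] <- shared[j, i] <- sum(ok)
      if (any(ok)) {
        d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
      } else {
        d[i, j] <- d[j, i] <- NA_real_
      }
    }
  }
  no_overlap <- is.na(d); diag(no_overlap) <- FALSE
  if (any(no_overlap)) {
    mx <- max(d, na.rm = TRUE)
    d[no_overlap] <- mx
  }
  attr(d, "no_overlap") <- no_overlap
  d
}

#' Neighbor-joining tree from a taxon matrix
#'
#' Internal surrogate for an external maximum-likelihood analysis: builds
#' the NJ tree (via \pkg{ape}) on p-distances with pairwise deletion.
#' Intended for subgenome label assignment and simulation tests; exported
#' PHYLIP matrices remain the route to full ML inference.
#'
#' @param mat character matrix taxa x sites (`NA` missing), >= 3 taxa.
#' @return an [ape::nj()] `phylo` tree with the distance matrix attached as
#'   attribute `distances`.
#' @export
nj_tree <- function(mat) {
  if (nrow(mat) < 3L) stop("need at least 3 taxa for a tree")
  d <- p_distance_matrix(mat)
  tr <- ape::nj(stats::as.dist(d))
  attr(tr, "distances") <- d
  tr
}

#' Assign Av/Bi/B1/B2 subgenome labels from a labeled tree
#'
#' For each parental map, the four homeologous linkage groups of one
#' haploid chromosome are labeled from the tree rooted on the outgroup:
#' the group inside the minimal clade containing the vesca-like diploid
#' (and not the iinumae-like diploid) is `Av`; among the remaining three,
#' the group in the minimal clade containing the iinumae-like diploid is
#' `Bi`; of the final two, the group with the greater mean p-distance to
#' the iinumae-like diploid is `B1`, the other `B2` (a tie is flagged and
#' broken deterministically by group id). Topologies inconsistent with the
#' one-Av/three-B structure yield `"unresolved"` labels rather than
#' guesses.
#'
#' @param tree `phylo` tree from [nj_tree()] containing the groups, the
#'   two ingroup diploids and at least one outgroup taxon.
#' @param group_map data.frame with columns `group` (tip label) and `map`
#'   (parental map id); groups of the same map are labeled jointly.
#' @param vesca_taxon,iinumae_taxon,outgroup_taxon tip labels of the
#'   reference diploids and the rooting outgroup.
#' @return data.frame with columns `group`, `map`, `label` and logical
#'   `tie`.
#' @export
assign_subgenome_labels <- function(tree, group_map, vesca_taxon,
                                    iinumae_taxon, outgroup_taxon) {
  stopifnot(all(c(vesca_taxon, iinumae_taxon, outgroup_taxon)
                %in% tree$tip.label))
  d <- attr(tree, "distances")
  rt <- ape::root(tree, outgroup = outgroup_taxon, resolve.root = TRUE)
  out <- NULL
  for (mp in unique(group_map$map)) {
    grps <- group_map$group[group_map$map == mp]
    grps <- grps[grps %in% tree$tip.label]
    lab <- rep("unresolved", length(grps))
    tie <- rep(FALSE, length(grps))
    names(lab) <- names(tie) <- grps
    av <- grps[vapply(grps, function(g) {
      .in_minimal_clade(rt, g, vesca_taxon, iinumae_taxon)
    }, logical(1))]
    if (length(av) == 1L) lab[av] <- "Av"
    rest <- setdiff(grps, av)
    bi <- rest[vapply(rest, function(g) {
      .in_minimal_clade(rt, g, iinumae_taxon, vesca_taxon,
                        restrict = setdiff(rest, g))
    }, logical(1))]
    if (length(bi) == 1L) lab[bi] <- "Bi"
    final <- setdiff(rest, bi)
    if (length(final) == 2L && length(bi) == 1L && !is.null(d)) {
      div <- d[final, iinumae_taxon]
      if (div[1L] == div[2L]) {
        tie[final] <- TRUE
        final <- final[order(final)]
      } else {
        final <- final[order(-div)]
      }
      lab[final[1L]] <- "B1"
      lab[final[2L]] <- "B2"
    }
    out <- rbind(out, data.frame(group = grps, map = mp,
                                 label = unname(lab), tie = unname(tie),
                                 stringsAsFactors = FALSE))
  }
  out
}

# is `tip` inside the smallest clade of `rooted` containing `anchor` that
# excludes `exclude`? Optionally ignore other candidate tips in `restrict`
# when measuring clade minimality (so sister-ness is judged per candidate).
.in_minimal_clade <- function(rooted, tip, anchor, exclude, restrict = NULL) {
  mrca <- ape::getMRCA(rooted, c(tip, anchor))
  if (is.null(mrca)) return(FALSE)
  clade <- ape::extract.clade(rooted, mrca)$tip.label
  if (exclude %in% clade) return(FALSE)
  if (!is.null(restrict) && any(restrict %in% clade)) return(FALSE)
  TRUE
}

#' Fraction of missing cells in a taxon matrix (or list of matrices)
#'
#' @param mats a matrix or list of matrices from [build_taxon_matrix()].
#' @return fraction of `NA` cells across all matrices.
#' @export
missing_fraction <- function(mats) {
  if (is.matrix(mats)) mats <- list(mats)
  tot <- sum(vapply(mats, length, numeric(1)))
  mis <- sum(vapply(mats, function(m) sum(is.na(m)), numeric(1)))
  mis / tot
}
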
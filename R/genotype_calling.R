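#' Threshold-based octoploid genotype call from base counts
#'
#' Calls a single site in a single octoploid sample from its A/C/G/T counts.
#' The caller targets variants heterozygous at a single homeolog, which are
#' expected near one-eighth allele frequency:
#' * depth below `min_depth` (default 32) is `MISSING`;
#' * `HET` when the rare variant is seen at least twice and at >= 2.5%
#'   frequency;
#' * `HOM` when there is no second allele, or the rare variant is seen
#'   exactly once at < 1.25% frequency (treated as sequencing error);
#' * anything in between (ambiguous evidence) is `MISSING`.
#'
#' Frequencies are compared with integer arithmetic (`count * 10000` versus
#' `depth * 250` / `depth * 125`) so the 2.5%/1.25% boundaries are exact.
#' A tie between two non-major alleles is coded `MISSING`: the model assumes
#' a biallelic rare variant.
#'
#' @param counts named numeric vector with elements `A`, `C`, `G`, `T`.
#' @param min_depth minimum A/C/G/T depth for a call (default 32).
#' @return list with `state` (`"HOM"`, `"HET"` or `"MISSING"`),
#'   `major_allele`, `minor_allele` (NA unless HET), `minor_count`, `depth`.
#' @examples
#' call_octoploid_genotype(c(A = 78, C = 0, G = 0, T = 2))  # HET, T
#' call_octoploid_genotype(c(A = 199, C = 0, G = 0, T = 1)) # HOM
#' @export
call_octoploid_genotype <- function(counts, min_depth = 32) {
  counts <- as.integer(counts[c("A", "C", "G", "T")])
  names(counts) <- c("A", "C", "G", "T")
  depth <- sum(counts)
  res <- list(state = "MISSING", major_allele = NA_character_,
              minor_allele = NA_character_, minor_count = NA_integer_,
              depth = depth)
  if (depth < min_depth) return(res)
  ord <- order(-counts, names(counts))   # alphabetical tie-break
  major <- names(counts)[ord[1L]]
  minor <- names(counts)[ord[2L]]
  mc <- counts[[ord[2L]]]
  third <- counts[[ord[3L]]]
  res$major_allele <- major
  res$minor_count <- mc
  if (mc > 0L && third == mc) return(res)  # non-major tie: not biallelic
  if (mc == 0L) {
    res$state <- "HOM"
  } else if (mc >= 2L && mc * 10000L >= depth * 250L) {
    res$state <- "HET"
    res$minor_allele <- minor
  } else if (mc == 1L && mc * 10000L < depth * 125L) {
    res$state <- "HOM"
  }
  res
}

#' Vectorised octoploid genotype calling over a count matrix
#'
#' Applies the same rules as [call_octoploid_genotype()] to every row of an
#' n-by-4 count matrix.
#'
#' @param counts integer matrix with columns `A`, `C`, `G`, `T`.
#' @param min_depth minimum depth for a call.
#' @return data.frame with columns `state`, `major_allele`, `minor_allele`,
#'   `minor_count`, `depth`, one row per input row.
#' @export
call_octoploid_genotypes <- function(counts, min_depth = 32) {
  counts <- as.matrix(counts[, c("A", "C", "G", "T"), drop = FALSE])
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  bases <- c("A", "C", "G", "T")
  depth <- rowSums(counts)
  state <- rep("MISSING", n)
  major <- minor <- rep(NA_character_, n)
  mc <- rep(NA_integer_, n)
  if (n > 0L) {
    # per-row order of the four counts, alphabetical tie-break
    rk <- t(apply(counts, 1L, function(x) order(-x, bases)))
    idx1 <- cbind(seq_len(n), rk[, 1L])
    idx2 <- cbind(seq_len(n), rk[, 2L])
    idx3 <- cbind(seq_len(n), rk[, 3L])
    c2 <- counts[idx2]; c3 <- counts[idx3]
    ok <- depth >= min_depth
    tie <- c2 > 0L & c3 == c2
    hom0 <- ok & !tie & c2 == 0L
    het <- ok & !tie & c2 >= 2L & c2 * 10000L >= depth * 250L
    hom1 <- ok & !tie & c2 == 1L & c2 * 10000L < depth * 125L
    state[hom0 | hom1] <- "HOM"
    state[het] <- "HET"
    major[ok] <- bases[rk[, 1L]][ok]
    minor[het] <- bases[rk[, 2L]][het]
    mc[ok] <- c2[ok]
  }
  data.frame(state = state, major_allele = major, minor_allele = minor,
             minor_count = mc, depth = depth, stringsAsFactors = FALSE)
}

#' Select linkage-map markers (LG SNPs) with Mendelian and missingness filters
#'
#' A site becomes a candidate LG SNP when at least one parent is
#' heterozygous. Sites heterozygous in exactly one parent are retained for
#' mapping when both progeny genotype classes (HET and HOM) are observed in
#' at least `min_per_class` progeny and at most `max_missing` progeny are
#' missing. Sites heterozygous in both parents are never mapped; they are
#' routed to a separate biparental set used downstream to pair corresponding
#' maternal and paternal linkage groups.
#'
#' @param parent_states character matrix, sites x 2 parents, values
#'   `"HOM"`/`"HET"`/`"MISSING"`; column names are taken as parent labels
#'   (default `maternal`, `paternal`).
#' @param progeny_states character matrix, sites x progeny, same coding.
#' @param site_info data.frame with one row per site, at least `chrom` and
#'   `pos`; carried through to the output.
#' @param parent_minor optional character matrix (sites x 2) of the parents'
#'   minor alleles, carried through for retained sites.
#' @param min_per_class minimum progeny per genotype class (default 8).
#' @param max_missing maximum missing progeny (default 1).
#' @return list with elements `lg_snps` (data.frame: site_info columns,
#'   `parent` = `"maternal"`/`"paternal"`, `minor_allele`, `n_het`, `n_hom`,
#'   `n_missing`, plus a `segregation` character string of `1`/`0`/`-` per
#'   progeny) and `biparental` (data.frame of sites heterozygous in both
#'   parents).
#' @export
select_lg_snps <- function(parent_states, progeny_states, site_info,
                           parent_minor = NULL,
                           min_per_class = 8, max_missing = 1) {
  parent_states <- as.matrix(parent_states)
  progeny_states <- as.matrix(progeny_states)
  if (ncol(progeny_states) < 2 * min_per_class) {
    stop("need at least ", 2 * min_per_class,
         " progeny for the per-class filter to be satisfiable")
  }
  stopifnot(nrow(parent_states) == nrow(progeny_states),
            nrow(site_info) == nrow(progeny_states),
            ncol(parent_states) == 2L)
  plab <- colnames(parent_states)
  if (is.null(plab)) plab <- c("maternal", "paternal")
  het_m <- parent_states[, 1L] == "HET"
  het_p <- parent_states[, 2L] == "HET"
  n_het <- rowSums(progeny_states == "HET")
  n_hom <- rowSums(progeny_states == "HOM")
  n_mis <- rowSums(progeny_states == "MISSING")
  bipar <- het_m & het_p
  mono <- xor(het_m, het_p)
  keep <- mono & n_het >= min_per_class & n_hom >= min_per_class &
    n_mis <= max_missing
  seg_string <- function(rows) {
    apply(progeny_states[rows, , drop = FALSE], 1L, function(x) {
      paste(ifelse(x == "HET", "1", ifelse(x == "HOM", "0", "-")),
            collapse = "")
    })
  }
  lg <- site_info[keep, , drop = FALSE]
  if (nrow(lg) > 0L) {
    lg$parent <- ifelse(het_m[keep], plab[1L], plab[2L])
    lg$minor_allele <- if (is.null(parent_minor)) NA_character_ else
      ifelse(het_m[keep], parent_minor[keep, 1L], parent_minor[keep, 2L])
    lg$n_het <- n_het[keep]; lg$n_hom <- n_hom[keep]
    lg$n_missing <- n_mis[keep]
    lg$segregation <- seg_string(which(keep))
  }
  bi <- site_info[bipar, , drop = FALSE]
  if (nrow(bi) > 0L) {
    bi$minor_maternal <- if (is.null(parent_minor)) NA_character_ else
      parent_minor[bipar, 1L]
    bi$minor_paternal <- if (is.null(parent_minor)) NA_character_ else
      parent_minor[bipar, 2L]
  }
  rownames(lg) <- rownames(bi) <- NULL
  list(lg_snps = lg, biparental = bi)
}

#' Diploid site filter on Phred-scaled genotype likelihoods
#'
#' Per-individual genotypes are valid only when depth >= `min_depth`, the
#' best Phred-scaled likelihood (PL) is 0 and every other PL is
#' >= `min_other_pl` (likelihood of any other genotype <= 1e-4 at the
#' default 40). A site is retained for mapping when fewer than
#' `max_missing_offspring` offspring are missing, no single genotype class
#' exceeds `max_class_fraction` of the called offspring, and the offspring
#' genotype set is producible from the parental genotypes under Mendelian
#' inheritance (biallelic dosage coding 0/1/2).
#'
#' @param pl numeric array individuals x genotypes (3 columns for a
#'   biallelic site, dosage order 0,1,2) of Phred-scaled likelihoods;
#'   first `n_parents` rows are the parents, the rest offspring.
#' @param depths per-individual read depths.
#' @param n_parents number of leading parent rows (2, or 1 for a selfed
#'   cross where the single parent is both donors).
#' @param min_depth per-individual depth cutoff (default 20).
#' @param min_other_pl PL cutoff for non-best genotypes (default 40).
#' @param max_missing_offspring strict upper bound on missing offspring
#'   (default 8: "fewer than eight").
#' @param max_class_fraction maximum fraction of offspring in one genotype
#'   class (default 0.85; strictly-greater rejects).
#' @return list with `retained` flag, per-individual `genotype` (dosage or
#'   NA) and a `reason` string when rejected.
#' @export
filter_diploid_site <- function(pl, depths, n_parents = 2,
                                min_depth = 20, min_other_pl = 40,
                                max_missing_offspring = 8,
                                max_class_fraction = 0.85) {
  pl <- as.matrix(pl)
  n <- nrow(pl)
  stopifnot(length(depths) == n, n_parents >= 1, n > n_parents)
  geno <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    o <- sort(pl[i, ])
    if (depths[i] >= min_depth && o[1L] == 0 && o[2L] >= min_other_pl) {
      geno[i] <- which.min(pl[i, ]) - 1L
    }
  }
  par_g <- geno[seq_len(n_parents)]
  off_g <- geno[-seq_len(n_parents)]
  n_off <- length(off_g)
  reject <- function(why) list(retained = FALSE, genotype = geno, reason = why)
  if (sum(is.na(off_g)) >= max_missing_offspring) {
    return(reject("too many missing offspring"))
  }
  called <- off_g[!is.na(off_g)]
  if (length(called) == 0L) return(reject("no called offspring"))
  if (max(table(called)) > max_class_fraction * length(called)) {
    return(reject("offspring too uniform"))
  }
  if (any(is.na(par_g))) return(reject("uninformative parents"))
  if (n_parents == 1L) par_g <- c(par_g, par_g)
  possible <- .mendelian_offspring(par_g[1L], par_g[2L])
  if (!all(called %in% possible)) return(reject("non-Mendelian segregation"))
  if (length(possible) < 2L) return(reject("uninformative parents"))
  list(retained = TRUE, genotype = geno, reason = NA_character_)
}

.mendelian_offspring <- function(g1, g2) {
  gametes <- function(g) switch(as.character(g),
                                "0" = 0L, "2" = 1L, "1" = c(0L, 1L))
  sort(unique(as.vector(outer(gametes(g1), gametes(g2), `+`))))
}

#' Chain nearby SNP positions into 1-kb marker regions
#'
#' Single-linkage chaining: consecutive sorted positions closer than `gap`
#' base pairs share a region; a difference of `gap` or more starts a new
#' region. This mirrors the width of the high-coverage sequence captured by
#' one probe set, so SNPs in a region are treated as one locus in
#' region-level analyses.
#'
#' @param positions sorted ascending integer positions on one chromosome.
#' @param gap region-breaking distance in bp (default 1000).
#' @return integer vector of region ids (1-based, same length as input).
#' @examples
#' group_regions(c(1000, 1900, 3100))  # 1 1 2
#' @export
group_regions <- function(positions, gap = 1000) {
  if (length(positions) == 0L) return(integer(0))
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  c(1L, cumsum(diff(positions) >= gap) + 1L)
}

#' Region ids for a table of SNPs across chromosomes
#'
#' Applies [group_regions()] per chromosome and returns globally unique
#' region ids of the form `chrom:index`.
#'
#' @param chrom chromosome per SNP.
#' @param pos position per SNP (need not be pre-sorted; sorting is internal).
#' @param gap region-breaking distance in bp.
#' @return character vector of region ids aligned with the input order.
#' @export
assign_region_ids <- function(chrom, pos, gap = 1000) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    o <- order(pos[idx])
    ids <- group_regions(pos[idx][o], gap = gap)
    out[idx[o]] <- paste0(ch, ":", ids)
  }
  out
}
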
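#' Classify one informative site against the subgenome phylogeny
#'
#' Requires a non-missing base for the subgenome, the vesca-like diploid,
#' the iinumae-like diploid and an outgroup. Only two-state 2:2 patterns
#' are informative:
#' * `SUPPORTIVE`: the subgenome shares a base with its sister ingroup
#'   species while the other two taxa share a different base;
#' * `INTROGRESSION_LIKE`: the subgenome shares a base with the wrong
#'   ingroup species while its sister shares a different base with the
#'   outgroup;
#' * `OUTGROUP_HOMOPLASY`: the subgenome shares a base with the outgroup
#'   while the two ingroup diploids share a different base.
#' All other patterns (invariant, 3:1, more than two states) are
#' `UNINFORMATIVE`. Only the partition of the four bases matters, never
#' their identities.
#'
#' @param subgenome_base,vesca_base,iinumae_base,outgroup_base single
#'   nucleotide characters (any NA gives `UNINFORMATIVE`).
#' @param sister which ingroup diploid the subgenome is sister to:
#'   `"vesca"` (the Av subgenome) or `"iinumae"` (Bi/B1/B2).
#' @return one of `"SUPPORTIVE"`, `"INTROGRESSION_LIKE"`,
#'   `"OUTGROUP_HOMOPLASY"`, `"UNINFORMATIVE"`.
#' @export
classify_site <- function(subgenome_base, vesca_base, iinumae_base,
                          outgroup_base, sister = c("iinumae", "vesca")) {
  sister <- match.arg(sister)
  s <- subgenome_base; v <- vesca_base; i <- iinumae_base; o <- outgroup_base
  if (any(is.na(c(s, v, i, o)))) return("UNINFORMATIVE")
  sis <- if (sister == "vesca") v else i
  oth <- if (sister == "vesca") i else v
  if (s == sis && oth == o && s != o) return("SUPPORTIVE")
  if (s == oth && sis == o && s != o) return("INTROGRESSION_LIKE")
  if (s == o && v == i && s != v) return("OUTGROUP_HOMOPLASY")
  "UNINFORMATIVE"
}

#' Classify a 1-kb region from its member site classes
#'
#' Per parental sample: a region holding both supportive and
#' introgression-like sites is `SUPPORT_HOMOPLASY` (internally conflicted,
#' treated as not showing true introgression); only introgression-like
#' (with or without outgroup-homoplasy sites) is `INTROGRESSION_LIKE`;
#' only supportive (with or without outgroup) is `SUPPORTIVE`; only
#' outgroup-homoplasy is `OUTGROUP`. A region with no informative site is
#' `NA` (omitted upstream).
#'
#' @param site_classes character vector of [classify_site()] results for
#'   the region's sites (one parental sample).
#' @return region class string or `NA_character_`.
#' @export
classify_region <- function(site_classes) {
  site_classes <- site_classes[site_classes != "UNINFORMATIVE"]
  if (length(site_classes) == 0L) return(NA_character_)
  has_s <- any(site_classes == "SUPPORTIVE")
  has_i <- any(site_classes == "INTROGRESSION_LIKE")
  has_o <- any(site_classes == "OUTGROUP_HOMOPLASY")
  if (has_s && has_i) return("SUPPORT_HOMOPLASY")
  if (has_i) return("INTROGRESSION_LIKE")
  if (has_s) return("SUPPORTIVE")
  if (has_o) return("OUTGROUP")
  NA_character_
}

#' Detect introgression clusters along one subgenome of one chromosome
#'
#' Scans an ordered track of region calls for maximal windows that start
#' and end at `INTROGRESSION_LIKE` regions, contain at least
#' `min_regions` of them, and in which the count of introgression-like
#' regions is at least `min_ratio` times the count of supportive-side
#' regions (`SUPPORTIVE` plus `SUPPORT_HOMOPLASY`; a zero supportive-side
#' count always satisfies the ratio). `OUTGROUP` regions are neutral:
#' they neither support nor break a window. Overlapping qualifying
#' windows are merged, so reported clusters never overlap each other.
#'
#' @param region_calls data.frame ordered by position with columns
#'   `class` (region call), `start`, `end` (first/last marker site of the
#'   region) and optionally `maps` (list-column of contributing map ids).
#' @param min_regions minimum introgression-like regions per cluster
#'   (default 2).
#' @param min_ratio minimum introgression:supportive ratio (default 4).
#' @return data.frame with one row per cluster: `start`, `end` (first to
#'   last marker site over member regions), `n_regions`
#'   (introgression-like count), `maps` (comma-joined union of
#'   contributing maps of the introgression-like members).
#' @export
detect_clusters <- function(region_calls, min_regions = 2, min_ratio = 4) {
  cls <- region_calls$class
  n <- length(cls)
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_regions = integer(0), maps = character(0))
  if (n == 0L) return(empty)
  if (is.unsorted(region_calls$start)) {
    stop("region calls must be ordered by position")
  }
  is_i <- cls == "INTROGRESSION_LIKE"
  is_sup <- cls %in% c("SUPPORTIVE", "SUPPORT_HOMOPLASY")
  ci <- cumsum(is_i); cs <- cumsum(is_sup)
  idx_i <- which(is_i)
  member <- rep(FALSE, n)
  for (a in idx_i) {
    for (b in idx_i[idx_i >= a]) {
      ni <- ci[b] - ci[a] + is_i[a]
      ns <- cs[b] - cs[a] + is_sup[a]
      if (ni >= min_regions && (ns == 0L || ni >= min_ratio * ns)) {
        member[a:b] <- TRUE
      }
    }
  }
  if (!any(member)) return(empty)
  runs <- rle(member)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- NULL
  for (k in which(runs$values)) {
    w <- starts[k]:ends[k]
    wi <- w[is_i[w]]
    maps <- if ("maps" %in% names(region_calls)) {
      paste(sort(unique(unlist(region_calls$maps[wi]))), collapse = ",")
    } else {
      NA_character_
    }
    out <- rbind(out, data.frame(
      start = min(region_calls$start[wi]),
      end = max(region_calls$end[wi]),
      n_regions = length(wi), maps = maps, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Brute-force reference for [detect_clusters()]
#'
#' Enumerates every contiguous window explicitly and merges qualifying
#' ones. Used as the independent oracle in tests; identical output
#' contract.
#'
#' @inheritParams detect_clusters
#' @export
detect_clusters_bruteforce <- function(region_calls, min_regions = 2,
                                       min_ratio = 4) {
  cls <- region_calls$class
  n <- length(cls)
  member <- rep(FALSE, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)[seq_len(n) >= a]) {
      w <- a:b
      if (cls[a] != "INTROGRESSION_LIKE") next
      if (cls[b] != "INTROGRESSION_LIKE") next
      ni <- sum(cls[w] == "INTROGRESSION_LIKE")
      ns <- sum(cls[w] %in% c("SUPPORTIVE", "SUPPORT_HOMOPLASY"))
      if (ni >= min_regions && (ns == 0 || ni >= min_ratio * ns)) {
        member[w] <- TRUE
      }
    }
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_regions = integer(0), maps = character(0))
  if (!any(member)) return(empty)
  runs <- rle(member)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- NULL
  for (k in which(runs$values)) {
    w <- starts[k]:ends[k]
    wi <- w[cls[w] == "INTROGRESSION_LIKE"]
    maps <- if ("maps" %in% names(region_calls)) {
      paste(sort(unique(unlist(region_calls$maps[wi]))), collapse = ",")
    } else {
      NA_character_
    }
    out <- rbind(out, data.frame(
      start = min(region_calls$start[wi]),
      end = max(region_calls$end[wi]),
      n_regions = length(wi), maps = maps, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Excess of introgression-like over outgroup homoplasy
#'
#' Without introgression both homoplasy classes arise from the same noise
#' processes (independent mutation, incomplete lineage sorting, sequencing
#' error) and should be equally common; an excess of the
#' introgression-like class signals gene flow (an ABBA/BABA-style
#' contrast). The primary test is an exact two-sided binomial test of the
#' introgression-like count against proportion 0.5; a Fisher variant
#' against a rounded 50:50 expected row is reported alongside.
#'
#' @param n_introgression_like,n_outgroup nonnegative counts.
#' @return list with `ratio` (`Inf` flagged when the outgroup count is 0),
#'   `p_binomial`, `p_fisher`; all `NA` when both counts are zero.
#' @export
excess_homoplasy_test <- function(n_introgression_like, n_outgroup) {
  ni <- n_introgression_like; no <- n_outgroup
  if (ni + no == 0) {
    return(list(ratio = NA_real_, p_binomial = NA_real_,
                p_fisher = NA_real_))
  }
  ratio <- if (no == 0) Inf else ni / no
  pb <- stats::binom.test(ni, ni + no, p = 0.5)$p.value
  half <- round((ni + no) / 2)
  pf <- stats::fisher.test(matrix(c(ni, no, half, ni + no - half),
                                  nrow = 2, byrow = TRUE))$p.value
  list(ratio = ratio, p_binomial = pb, p_fisher = pf)
}

#' Directionality test for introgression clusters
#'
#' Of the four subgenomes, three are iinumae-like (can gain vesca-like
#' sequence) and one is vesca-like (can gain iinumae-like sequence), so
#' under direction-neutral introgression cluster counts should split 3:1.
#' Fisher's exact test compares the observed split with the rounded 3:1
#' expectation at the observed total.
#'
#' @param clusters_toward_vesca clusters converting an iinumae-like
#'   subgenome toward vesca.
#' @param clusters_toward_iinumae clusters converting Av toward iinumae.
#' @return list with the 2x2 `table` and `p`.
#' @export
directionality_test <- function(clusters_toward_vesca,
                                clusters_toward_iinumae) {
  total <- clusters_toward_vesca + clusters_toward_iinumae
  stopifnot(total >= 1)
  exp_v <- round(0.75 * total)
  tab <- matrix(c(clusters_toward_vesca, clusters_toward_iinumae,
                  exp_v, total - exp_v), nrow = 2, byrow = TRUE,
                dimnames = list(c("observed", "expected"),
                                c("toward_vesca", "toward_iinumae")))
  list(table = tab, p = stats::fisher.test(tab)$p.value)
}

#' Summary geometry of a set of introgression clusters
#'
#' Spans are `end - start` in bp (matching the kb spans usually printed
#' for marker-site intervals). The genomic union merges intervals across
#' subgenomes per chromosome; the cross-subgenome overlap statistics count
#' pairwise intersections between clusters on different subgenomes and
#' sum their merged extent.
#'
#' @param clusters data.frame with columns `chrom`, `start`, `end`,
#'   `subgenome`.
#' @return list with `n`, `span_min`, `span_median`, `span_mean`,
#'   `span_max` (bp), `union` (bp), `overlap_instances`, `overlap_extent`
#'   (bp).
#' @export
cluster_geometry <- function(clusters) {
  sp <- clusters$end - clusters$start
  merge_len <- function(s, e) {
    o <- order(s); s <- s[o]; e <- e[o]
    tot <- 0; cs <- s[1L]; ce <- e[1L]
    for (i in seq_along(s)[-1L]) {
      if (s[i] <= ce) ce <- max(ce, e[i]) else {
        tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i]
      }
    }
    tot + (ce - cs)
  }
  un <- sum(vapply(unique(clusters$chrom), function(ch) {
    r <- clusters[clusters$chrom == ch, ]
    merge_len(r$start, r$end)
  }, numeric(1)))
  n <- nrow(clusters)
  ov_s <- ov_e <- ov_ch <- NULL
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (clusters$chrom[i] == clusters$chrom[j] &&
            clusters$subgenome[i] != clusters$subgenome[j]) {
          s <- max(clusters$start[i], clusters$start[j])
          e <- min(clusters$end[i], clusters$end[j])
          if (s < e) {
            ov_s <- c(ov_s, s); ov_e <- c(ov_e, e); ov_ch <- c(ov_ch,
                                                              clusters$chrom[i])
          }
        }
      }
    }
  }
  ov_extent <- if (is.null(ov_s)) 0 else {
    sum(vapply(unique(ov_ch), function(ch) {
      merge_len(ov_s[ov_ch == ch], ov_e[ov_ch == ch])
    }, numeric(1)))
  }
  list(n = n, span_min = min(sp), span_median = stats::median(sp),
       span_mean = mean(sp), span_max = max(sp), union = un,
       overlap_instances = length(ov_s), overlap_extent = ov_extent)
}

#' Allele-depth-ratio corroboration of introgression clusters
#'
#' At SNPs distinguishing the vesca-like and iinumae-like diploids, the
#' combined parental read depth of the two alleles measures the relative
#' representation of vesca-like sequence among the eight homeologs. Sites
#' are kept when combined depth lies in `[min_depth, max_depth]` and the
#' vesca:iinumae depth ratio within `[1/max_ratio, max_ratio]` (extreme
#' ratios are treated as mapping artifacts). Mean ratios are reported per
#' genomic bin and an unequal-variance two-sample t test compares
#' in-cluster against out-of-cluster sites.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `vesca_depth`,
#'   `iinumae_depth`.
#' @param clusters data.frame with `chrom`, `start`, `end`.
#' @param bin bin width in bp (default 1e6).
#' @param min_depth,max_depth combined-depth window (defaults 45, 200).
#' @param max_ratio ratio cap (default 8).
#' @return list with `sites` (retained sites with `ratio` and
#'   `in_cluster`), `bins` (per-bin mean ratio) and `test` (Welch t
#'   statistic and p, or NA when a side has fewer than 2 sites).
#' @export
allele_depth_ratio <- function(sites, clusters, bin = 1e6,
                               min_depth = 45, max_depth = 200,
                               max_ratio = 8) {
  comb <- sites$vesca_depth + sites$iinumae_depth
  keep <- comb >= min_depth & comb <= max_depth & sites$iinumae_depth > 0
  s <- sites[keep, , drop = FALSE]
  s$ratio <- s$vesca_depth / s$iinumae_depth
  s <- s[s$ratio <= max_ratio & s$ratio >= 1 / max_ratio, , drop = FALSE]
  s$in_cluster <- vapply(seq_len(nrow(s)), function(i) {
    any(clusters$chrom == s$chrom[i] & clusters$start <= s$pos[i] &
          clusters$end >= s$pos[i])
  }, logical(1))
  s$bin <- paste0(s$chrom, ":", floor((s$pos - 1) / bin))
  bins <- stats::aggregate(ratio ~ bin + chrom, data = s, FUN = mean)
  test <- list(t = NA_real_, p = NA_real_,
               mean_in = NA_real_, mean_out = NA_real_)
  if (sum(s$in_cluster) >= 2 && sum(!s$in_cluster) >= 2) {
    tt <- stats::t.test(s$ratio[s$in_cluster], s$ratio[!s$in_cluster])
    test <- list(t = unname(tt$statistic), p = tt$p.value,
                 mean_in = mean(s$ratio[s$in_cluster]),
                 mean_out = mean(s$ratio[!s$in_cluster]))
  }
  list(sites = s, bins = bins, test = test)
}

#' Polarized source-of-introgression counts
#'
#' For sites where an iinumae-like subgenome carries a derived allele
#' (relative to the outgroup) shared by either the vesca-like diploid or
#' the Av subgenome but not both, counts how often the subgenome groups
#' with vesca only versus Av only. Distinguishes pre-polyploidization
#' hybridization (vesca as donor) from post-polyploidization homeologous
#' exchange (Av as donor).
#'
#' @param sites data.frame with columns `b_base` (introgressed subgenome),
#'   `vesca_base`, `av_base`, `outgroup_base`.
#' @return list with counts `vesca_only` and `av_only`.
#' @export
source_informative_sites <- function(sites) {
  b <- sites$b_base; v <- sites$vesca_base
  a <- sites$av_base; o <- sites$outgroup_base
  ok <- !(is.na(b) | is.na(v) | is.na(a) | is.na(o))
  derived <- ok & b != o
  vesca_only <- derived & b == v & b != a
  av_only <- derived & b == a & b != v
  list(vesca_only = sum(vesca_only), av_only = sum(av_only))
}
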
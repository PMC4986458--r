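#' Detect interchromosomal rearrangement events
#'
#' An event is an LG SNP whose reference chromosome differs from the
#' primary chromosome of its linkage group: sequence that maps to one
#' place in the reference but segregates with another chromosome. Each
#' event is annotated with its nearest targeted region (distance 0 when
#' inside); the restricted set keeps events within `max_distance` of a
#' targeted region, standardising coverage for the permutation null.
#'
#' @param lg_snps data.frame with columns `chrom`, `pos`, `group`.
#' @param groups data.frame with columns `group`, `primary_chromosome`.
#' @param targets data.frame with columns `chrom`, `start`, `end` (and
#'   optionally an id column `target`); may be `NULL` to skip annotation.
#' @param max_distance restriction distance in bp (default 1000).
#' @return data.frame of events: `chrom`, `pos`, `group`,
#'   `group_chromosome`, `nearest_target`, `target_distance`,
#'   `restricted` (logical).
#' @export
detect_rearrangements <- function(lg_snps, groups, targets = NULL,
                                  max_distance = 1000) {
  gchr <- groups$primary_chromosome[match(lg_snps$group, groups$group)]
  ev <- lg_snps[!is.na(gchr) & lg_snps$chrom != gchr, , drop = FALSE]
  ev$group_chromosome <- gchr[!is.na(gchr) & lg_snps$chrom != gchr]
  ev$nearest_target <- rep(NA_integer_, nrow(ev))
  ev$target_distance <- rep(NA_real_, nrow(ev))
  if (!is.null(targets) && nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      tt <- which(targets$chrom == ev$chrom[i])
      if (length(tt) == 0L) next
      d <- pmax(targets$start[tt] - ev$pos[i], ev$pos[i] - targets$end[tt], 0)
      j <- tt[which.min(d)]
      ev$nearest_target[i] <- j
      ev$target_distance[i] <- min(d)
    }
  }
  ev$restricted <- !is.na(ev$target_distance) &
    ev$target_distance <= max_distance
  rownames(ev) <- NULL
  ev
}

#' Permutation null for rearrangement clustering
#'
#' Distributes `n_events` rearrangements independently and uniformly among
#' `n_regions` targeted regions, `reps` times, and records per replicate
#' (a) the number of regions receiving two or more events and (b) the mean
#' over events of the number of co-occupants in the event's region.
#' Reported intervals are the empirical 2.5/97.5 percentiles. A
#' without-replacement variant (each replicate places events in distinct
#' regions) is available for sensitivity analysis; statistic (a) is then
#' always zero.
#'
#' @param n_events number of rearrangement events (>= 1).
#' @param n_regions number of targeted regions with LG SNPs (>= 1).
#' @param reps replicates (default 10000).
#' @param seed RNG seed for reproducibility.
#' @param replace logical; `TRUE` (default) assigns events independently.
#' @return list with `reps`, `seed`, `multi_regions`
#'   (mean/ci_low/ci_high of statistic a), `co_occupancy` (same for
#'   statistic b) and the per-replicate vectors `multi_regions_rep`,
#'   `co_occupancy_rep`.
#' @export
permutation_clustering_test <- function(n_events, n_regions, reps = 10000,
                                        seed = NULL, replace = TRUE) {
  stopifnot(n_events >= 1, n_regions >= 1)
  if (!replace && n_events > n_regions) {
    stop("cannot place events without replacement: more events than regions")
  }
  if (!is.null(seed)) set.seed(seed)
  multi <- numeric(reps)
  coocc <- numeric(reps)
  for (r in seq_len(reps)) {
    assign <- sample.int(n_regions, n_events, replace = replace)
    tab <- tabulate(assign, nbins = n_regions)
    multi[r] <- sum(tab >= 2L)
    coocc[r] <- mean(tab[assign] - 1L)
  }
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  list(reps = reps, seed = seed,
       multi_regions = list(mean = mean(multi), ci = ci(multi)),
       co_occupancy = list(mean = mean(coocc), ci = ci(coocc)),
       multi_regions_rep = multi, co_occupancy_rep = coocc)
}

#' Observed clustering statistics for a set of events
#'
#' Companion to [permutation_clustering_test()]: given the region id of
#' each (restricted) event, computes the observed number of regions with
#' two or more events and the observed mean co-occupancy.
#'
#' @param region_ids region identifier per event.
#' @return list with `n_events`, `n_occupied_regions`, `multi_regions`,
#'   `co_occupancy`.
#' @export
observed_clustering <- function(region_ids) {
  tab <- table(region_ids)
  cnt <- as.integer(tab[match(region_ids, names(tab))])
  list(n_events = length(region_ids),
       n_occupied_regions = length(tab),
       multi_regions = sum(tab >= 2L),
       co_occupancy = mean(cnt - 1L))
}

#' Normalize capture depths and form the octoploid:diploid ratio
#'
#' Each sample's depth at the central targeted sites is divided by that
#' sample's total over all central sites, removing library-size
#' differences (the normalized profile of a sample sums to 1 and is
#' invariant to uniform rescaling of its depths). The octoploid value per
#' region is the mean normalized depth across the octoploid parent
#' samples; the reported ratio is octoploid over diploid, with regions
#' where the diploid value is zero excluded (ratio `NA`).
#'
#' @param depths numeric matrix regions x samples of central-site depths.
#' @param octoploid_samples,diploid_sample column names (or indices).
#' @return list with `normalized` (matrix), `ratio` (per region, NA where
#'   undefined).
#' @export
normalize_depth <- function(depths, octoploid_samples, diploid_sample) {
  depths <- as.matrix(depths)
  tot <- colSums(depths)
  if (any(tot == 0)) stop("sample with all-zero depths")
  norm <- sweep(depths, 2L, tot, `/`)
  octo <- rowMeans(norm[, octoploid_samples, drop = FALSE])
  dip <- norm[, diploid_sample]
  ratio <- ifelse(dip > 0, octo / dip, NA_real_)
  list(normalized = norm, ratio = ratio)
}

#' Welch comparison of depth-ratio distributions
#'
#' Unequal-variance two-sample t test of the octoploid:diploid normalized
#' depth ratio between regions in a focal set (e.g., rearranged regions)
#' and the rest.
#'
#' @param ratios_in,ratios_out numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `mean_in`, `sd_in`, `mean_out`, `sd_out`.
#' @export
compare_ratio_distributions <- function(ratios_in, ratios_out) {
  ratios_in <- ratios_in[!is.na(ratios_in)]
  ratios_out <- ratios_out[!is.na(ratios_out)]
  if (length(ratios_in) < 2 || length(ratios_out) < 2) {
    stop("each set needs at least 2 ratios")
  }
  if (stats::sd(ratios_in) == 0 && stats::sd(ratios_out) == 0) {
    return(list(t = NA_real_, p = NA_real_,
                mean_in = mean(ratios_in), sd_in = 0,
                mean_out = mean(ratios_out), sd_out = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(ratios_in, ratios_out)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_in = mean(ratios_in), sd_in = stats::sd(ratios_in),
       mean_out = mean(ratios_out), sd_out = stats::sd(ratios_out),
       degenerate = FALSE)
}

#' In-silico PCR placement of primer pairs
#'
#' Finds genome placements where the forward primer matches one strand and
#' the reverse primer matches the opposite strand, facing inward, with
#' their 3' ends separated by at most `max_separation` bp. Matching is
#' exact by default (`max_mismatch = 0`); both orientations of the pair
#' are searched. Markers with no placement are dropped.
#'
#' @param primers data.frame with columns `marker`, `forward`, `reverse`
#'   (5'->3' nucleotide strings).
#' @param genome a named character vector of sequences or a
#'   [Biostrings::DNAStringSet].
#' @param max_separation maximum 3'-end separation in bp (default 2000).
#' @param max_mismatch allowed mismatches per primer (default 0).
#' @return data.frame of placements: `marker`, `chrom`, `start`, `end`
#'   (amplicon bounds), `length`, `strand` (`+` when the forward primer is
#'   on the plus strand).
#' @export
insilico_pcr <- function(primers, genome, max_separation = 2000,
                         max_mismatch = 0) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  out <- NULL
  for (i in seq_len(nrow(primers))) {
    fwd <- Biostrings::DNAString(primers$forward[i])
    rev <- Biostrings::DNAString(primers$reverse[i])
    for (ch in names(genome)) {
      subj <- genome[[ch]]
      hits <- function(pat) {
        m <- Biostrings::matchPattern(pat, subj,
                                      max.mismatch = max_mismatch)
        data.frame(start = Biostrings::start(m), end = Biostrings::end(m))
      }
      # plus orientation: fwd on +, reverse primer on - (its reverse
      # complement matches +, 3' end at the match start)
      f_p <- hits(fwd)
      r_p <- hits(Biostrings::reverseComplement(rev))
      for (a in seq_len(nrow(f_p))) {
        for (b in seq_len(nrow(r_p))) {
          sep <- r_p$start[b] - f_p$end[a]
          if (sep >= 0 && sep <= max_separation) {
            out <- rbind(out, data.frame(
              marker = primers$marker[i], chrom = ch,
              start = f_p$start[a], end = r_p$end[b],
              length = r_p$end[b] - f_p$start[a] + 1L, strand = "+",
              stringsAsFactors = FALSE))
          }
        }
      }
      # minus orientation: fwd on -, rev on +
      f_m <- hits(Biostrings::reverseComplement(fwd))
      r_m <- hits(rev)
      for (a in seq_len(nrow(f_m))) {
        for (b in seq_len(nrow(r_m))) {
          sep <- f_m$start[a] - r_m$end[b]
          if (sep >= 0 && sep <= max_separation) {
            out <- rbind(out, data.frame(
              marker = primers$marker[i], chrom = ch,
              start = r_m$start[b], end = f_m$end[a],
              length = f_m$end[a] - r_m$start[b] + 1L, strand = "-",
              stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(marker = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), strand = character(0))
  }
  out
}
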
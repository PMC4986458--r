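#' Pool per-map region calls into one call per region
#'
#' Region classification is done per parental map; a region's pooled call
#' combines them: any internally conflicted map (`SUPPORT_HOMOPLASY`), or
#' disagreement between a map calling introgression and a map calling
#' support, pools to `SUPPORT_HOMOPLASY`; otherwise any
#' `INTROGRESSION_LIKE` wins, then `SUPPORTIVE`, then `OUTGROUP`.
#'
#' @param calls character vector of per-map region calls.
#' @return single pooled class.
#' @export
pool_region_calls <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) return(NA_character_)
  has_h <- any(calls == "SUPPORT_HOMOPLASY")
  has_i <- any(calls == "INTROGRESSION_LIKE")
  has_s <- any(calls == "SUPPORTIVE")
  if (has_h || (has_i && has_s)) return("SUPPORT_HOMOPLASY")
  if (has_i) return("INTROGRESSION_LIKE")
  if (has_s) return("SUPPORTIVE")
  "OUTGROUP"
}

#' Region-count table in the style of a per-subgenome homoplasy summary
#'
#' Cross-tabulates pooled region calls by subgenome and chromosome into
#' rows `supportive`, `clustered_introgression` (regions inside detected
#' clusters), `clusters` (cluster counts), `isolated_introgression`,
#' `outgroup_homoplasy` and `support_homoplasy`, plus an `All`
#' `informative_regions` row.
#'
#' @param region_calls data.frame with columns `subgenome`, `chrom`,
#'   `region`, `class` (pooled) and logical `clustered` (inside a
#'   detected cluster).
#' @param clusters data.frame with columns `subgenome`, `chrom` (one row
#'   per cluster); may be empty.
#' @return data.frame with columns `signal`, `subgenome`, one column per
#'   chromosome, and `total`.
#' @export
make_table1 <- function(region_calls, clusters = NULL) {
  chroms <- sort(unique(region_calls$chrom))
  subgenomes <- c("Av", "Bi", "B1", "B2")
  subgenomes <- subgenomes[subgenomes %in% region_calls$subgenome]
  count_row <- function(signal, sg, sel) {
    cnt <- vapply(chroms, function(ch) sum(sel & region_calls$chrom == ch),
                  numeric(1))
    out <- data.frame(signal = signal, subgenome = sg,
                      stringsAsFactors = FALSE)
    out[chroms] <- as.list(cnt)
    out$total <- sum(cnt)
    out
  }
  rows <- NULL
  for (sg in subgenomes) {
    in_sg <- region_calls$subgenome == sg
    rows <- rbind(
      rows,
      count_row("supportive", sg, in_sg & region_calls$class == "SUPPORTIVE"),
      count_row("clustered_introgression", sg,
                in_sg & region_calls$class == "INTROGRESSION_LIKE" &
                  region_calls$clustered),
      {
        r <- count_row("clusters", sg, rep(FALSE, nrow(region_calls)))
        if (!is.null(clusters) && nrow(clusters) > 0L) {
          cc <- clusters[clusters$subgenome == sg, , drop = FALSE]
          for (ch in chroms) r[[ch]] <- sum(cc$chrom == ch)
          r$total <- nrow(cc)
        }
        r
      },
      count_row("isolated_introgression", sg,
                in_sg & region_calls$class == "INTROGRESSION_LIKE" &
                  !region_calls$clustered),
      count_row("outgroup_homoplasy", sg,
                in_sg & region_calls$class == "OUTGROUP"),
      count_row("support_homoplasy", sg,
                in_sg & region_calls$class == "SUPPORT_HOMOPLASY"))
  }
  # informative regions: distinct (chrom, region) with >=1 informative call
  inf <- unique(region_calls[!is.na(region_calls$class),
                             c("chrom", "region")])
  r <- data.frame(signal = "informative_regions", subgenome = "All",
                  stringsAsFactors = FALSE)
  for (ch in chroms) r[[ch]] <- sum(inf$chrom == ch)
  r$total <- nrow(inf)
  rbind(rows, r)
}

#' Headline summaries of a region-count table
#'
#' Verifies that every count row's per-chromosome entries sum to its
#' printed total and extracts the headline quantities: total supportive
#' regions for the vesca-like subgenome, total informative regions, the
#' introgression-like versus outgroup homoplasy counts and their ratio,
#' and the cluster tally.
#'
#' @param tab data.frame in the layout of [make_table1()] (chromosome
#'   columns between `subgenome` and `total`).
#' @return list with `sums_consistent`, `av_supportive`,
#'   `informative_regions`, `n_introgression_like`, `n_outgroup`,
#'   `ratio`, `n_clusters`, `n_clustered_regions`.
#' @export
table1_summary <- function(tab) {
  chrom_cols <- setdiff(names(tab), c("signal", "subgenome", "total"))
  count_rows <- tab$signal != "missing_pct"
  sums <- rowSums(tab[count_rows, chrom_cols, drop = FALSE])
  sums_consistent <- all(sums == tab$total[count_rows])
  pick <- function(signal, sg = NULL) {
    sel <- tab$signal == signal
    if (!is.null(sg)) sel <- sel & tab$subgenome == sg
    sum(tab$total[sel])
  }
  ni <- pick("clustered_introgression") + pick("isolated_introgression")
  no <- pick("outgroup_homoplasy")
  list(sums_consistent = sums_consistent,
       av_supportive = pick("supportive", "Av"),
       informative_regions = pick("informative_regions"),
       n_introgression_like = ni,
       n_outgroup = no,
       ratio = ni / no,
       n_clusters = pick("clusters"),
       n_clustered_regions = pick("clustered_introgression"))
}

#' Analyze a simulated (or equivalently structured) capture experiment
#'
#' Runs the full pipeline downstream of the pileup: octoploid genotype
#' calling, LG SNP selection, linkage grouping per parent, read-anchored
#' marker extraction, per-chromosome taxon matrices and NJ trees,
#' subgenome labeling, region classification, introgression cluster
#' detection with the excess-homoplasy and directionality tests, and the
#' interchromosomal rearrangement scan with its permutation null.
#'
#' @param sim output of [simulate_octoploid_experiment()] (with reads).
#' @param species_code code used in linkage-group names (default
#'   `"Foct"`).
#' @param lod_threshold,gap_cM,min_major linkage-group parameters.
#' @param perm_reps permutation replicates for the rearrangement test
#'   (default 1000 at desk scale).
#' @return list with the stage outputs: `calls`, `lg_snps`, `biparental`,
#'   `maps` (per-parent grouping), `groups` (annotated group table),
#'   `markers`, `matrices`, `trees`, `labels`, `region_calls`,
#'   `clusters`, `tests`, `rearrangements`, `log`.
#' @export
analyze_experiment <- function(sim, species_code = "Foct",
                               lod_threshold = 5, gap_cM = 33,
                               min_major = 5, perm_reps = 1000) {
  cfg <- sim$config
  sites <- sim$sites
  counts <- sim$counts
  samples <- unique(counts$sample)
  cross_samples <- setdiff(samples, "diploid_ref")
  progeny_samples <- grep("^F1_", cross_samples, value = TRUE)
  log <- character(0)

  # --- genotype calling ---
  site_key <- paste(sites$chrom, sites$pos)
  n_sites <- nrow(sites)
  state_mat <- matrix(NA_character_, n_sites, length(cross_samples),
                      dimnames = list(site_key, cross_samples))
  minor_mat <- state_mat
  for (s in cross_samples) {
    cs <- counts[counts$sample == s, , drop = FALSE]
    cs <- cs[match(site_key, paste(cs$chrom, cs$pos)), , drop = FALSE]
    gc <- call_octoploid_genotypes(cs[, c("A", "C", "G", "T")])
    state_mat[, s] <- gc$state
    minor_mat[, s] <- gc$minor_allele
  }

  # --- LG SNP selection ---
  snp_sel <- select_lg_snps(
    parent_states = state_mat[, c("maternal", "paternal"), drop = FALSE],
    progeny_states = state_mat[, progeny_samples, drop = FALSE],
    site_info = sites,
    parent_minor = minor_mat[, c("maternal", "paternal"), drop = FALSE])
  lg <- snp_sel$lg_snps
  if (nrow(lg) == 0L) stop("no LG SNPs retained; is the cross informative?")
  lg$region <- assign_region_ids(lg$chrom, lg$pos)

  # --- linkage groups per parent ---
  maps <- list()
  group_rows <- NULL
  lg$group <- NA_character_
  lg$cm <- NA_real_
  for (p in c("maternal", "paternal")) {
    sub <- which(lg$parent == p)
    seg <- do.call(rbind, lapply(strsplit(lg$segregation[sub], ""),
                                 function(x) {
                                   v <- suppressWarnings(as.integer(x))
                                   v
                                 }))
    rownames(seg) <- paste(lg$chrom[sub], lg$pos[sub])
    bl <- build_linkage_groups(seg, lg$chrom[sub], lg$pos[sub],
                               lod_threshold = lod_threshold,
                               gap_cM = gap_cM, min_major = min_major)
    maps[[p]] <- bl
    log <- c(log, paste0(p, ": ", bl$log))
    gid <- paste0(substr(p, 1, 1), bl$markers$group)
    lg$group[sub] <- gid
    lg$cm[sub] <- bl$markers$cm
    gr <- bl$groups
    gr$group <- paste0(substr(p, 1, 1), gr$group)
    gr$parent <- p
    group_rows <- rbind(group_rows, gr)
  }
  major_groups <- group_rows$group[group_rows$major]

  # --- anchored markers ---
  lg_major <- lg[lg$group %in% major_groups, , drop = FALSE]
  markers <- extract_anchored_markers(
    sim$reads, lg_major[, c("chrom", "pos", "minor_allele", "group")],
    sites, read_length = cfg$read_length)

  taxon_calls <- do.call(rbind, lapply(
    c("vesca", "iinumae", "outgroup"),
    function(tx) {
      data.frame(taxon = tx, chrom = sites$chrom, pos = sites$pos,
                 base = taxon_base(sim$lineages, tx, sites$chrom,
                                   sites$pos),
                 stringsAsFactors = FALSE)
    }))

  mats <- build_taxon_matrix(markers, taxon_calls, groups = major_groups)

  # --- trees and labels ---
  group_map <- data.frame(group = group_rows$group,
                          map = group_rows$parent,
                          stringsAsFactors = FALSE)
  trees <- list(); labels <- NULL
  for (ch in names(mats)) {
    present <- intersect(rownames(mats[[ch]]), major_groups)
    ch_groups <- group_rows$group[group_rows$primary_chromosome == ch &
                                    group_rows$group %in% present]
    if (length(ch_groups) == 0L) next
    keep <- c(ch_groups, "vesca", "iinumae", "outgroup")
    m <- mats[[ch]][intersect(keep, rownames(mats[[ch]])), , drop = FALSE]
    m <- m[, colSums(!is.na(m)) >= 1L, drop = FALSE]
    if (nrow(m) < 4L) next
    tr <- nj_tree(m)
    trees[[ch]] <- tr
    lab <- assign_subgenome_labels(
      tr, group_map[group_map$group %in% ch_groups, , drop = FALSE],
      "vesca", "iinumae", "outgroup")
    lab$chrom <- ch
    labels <- rbind(labels, lab)
  }
  group_rows$subgenome <- labels$label[match(group_rows$group,
                                             labels$group)]
  group_rows$name <- NA_character_
  for (i in seq_len(nrow(group_rows))) {
    sgl <- group_rows$subgenome[i]
    if (is.na(sgl) || !sgl %in% c("Av", "B1", "B2", "Bi")) next
    idx <- match(group_rows$primary_chromosome[i],
                 sort(unique(sites$chrom)))
    if (is.na(idx) || idx > 7) next
    group_rows$name[i] <- name_group(
      species_code, chromosome_numeral(idx), sgl,
      substr(group_rows$parent[i], 1, 1))
  }

  # --- site and region classification ---
  mk <- markers
  mk$subgenome <- group_rows$subgenome[match(mk$group, group_rows$group)]
  mk$map <- group_rows$parent[match(mk$group, group_rows$group)]
  mk <- mk[!is.na(mk$subgenome) & mk$subgenome %in% c("Av", "B1", "B2", "Bi"),
           , drop = FALSE]
  key <- paste(mk$chrom, mk$pos)
  tx_at <- function(tx) {
    tc <- taxon_calls[taxon_calls$taxon == tx, ]
    tc$base[match(key, paste(tc$chrom, tc$pos))]
  }
  mk$vesca <- tx_at("vesca"); mk$iinumae <- tx_at("iinumae")
  mk$outgroup <- tx_at("outgroup")
  mk$site_class <- vapply(seq_len(nrow(mk)), function(i) {
    classify_site(mk$base[i], mk$vesca[i], mk$iinumae[i], mk$outgroup[i],
                  sister = if (mk$subgenome[i] == "Av") "vesca" else
                    "iinumae")
  }, character(1))
  mk$region <- assign_region_ids(mk$chrom, mk$pos)

  region_calls <- NULL
  if (nrow(mk) > 0L) {
    key_map <- paste(mk$subgenome, mk$chrom, mk$region, mk$map, sep = "\r")
    per_map <- do.call(rbind, lapply(
      split(seq_len(nrow(mk)), key_map), function(ix) {
        d <- mk[ix, , drop = FALSE]
        data.frame(subgenome = d$subgenome[1L], chrom = d$chrom[1L],
                   region = d$region[1L], map = d$map[1L],
                   class = classify_region(d$site_class),
                   stringsAsFactors = FALSE)
      }))
    key_reg <- paste(per_map$subgenome, per_map$chrom, per_map$region,
                     sep = "\r")
    region_calls <- do.call(rbind, lapply(
      split(seq_len(nrow(per_map)), key_reg), function(ix) {
        d <- per_map[ix, , drop = FALSE]
        mkix <- mk$subgenome == d$subgenome[1L] &
          mk$chrom == d$chrom[1L] & mk$region == d$region[1L]
        data.frame(subgenome = d$subgenome[1L], chrom = d$chrom[1L],
                   region = d$region[1L],
                   class = pool_region_calls(d$class),
                   maps = I(list(sort(unique(d$map[!is.na(d$class)])))),
                   start = min(mk$pos[mkix]), end = max(mk$pos[mkix]),
                   stringsAsFactors = FALSE)
      }))
    region_calls <- region_calls[!is.na(region_calls$class), , drop = FALSE]
    rownames(region_calls) <- NULL
  }

  # --- clusters ---
  clusters <- NULL
  if (!is.null(region_calls) && nrow(region_calls) > 0L) {
    for (sg in unique(region_calls$subgenome)) {
      for (ch in unique(region_calls$chrom)) {
        track <- region_calls[region_calls$subgenome == sg &
                                region_calls$chrom == ch, , drop = FALSE]
        if (nrow(track) == 0L) next
        track <- track[order(track$start), , drop = FALSE]
        cl <- detect_clusters(track)
        if (nrow(cl) > 0L) {
          cl$subgenome <- sg; cl$chrom <- ch
          clusters <- rbind(clusters, cl)
        }
      }
    }
  }
  region_calls$clustered <- FALSE
  if (!is.null(clusters) && nrow(clusters) > 0L) {
    for (i in seq_len(nrow(clusters))) {
      sel <- region_calls$subgenome == clusters$subgenome[i] &
        region_calls$chrom == clusters$chrom[i] &
        region_calls$start >= clusters$start[i] &
        region_calls$end <= clusters$end[i] &
        region_calls$class == "INTROGRESSION_LIKE"
      region_calls$clustered[sel] <- TRUE
    }
  }

  # --- homoplasy and directionality tests ---
  ni <- sum(region_calls$class == "INTROGRESSION_LIKE")
  no <- sum(region_calls$class == "OUTGROUP")
  excess <- if (ni + no > 0) excess_homoplasy_test(ni, no) else NULL
  n_to_vesca <- if (is.null(clusters)) 0L else
    sum(clusters$subgenome %in% c("Bi", "B1", "B2"))
  n_to_iinumae <- if (is.null(clusters)) 0L else
    sum(clusters$subgenome == "Av")
  direction <- if (n_to_vesca + n_to_iinumae >= 1) {
    directionality_test(n_to_vesca, n_to_iinumae)
  } else {
    NULL
  }
  geometry <- if (!is.null(clusters) && nrow(clusters) > 0L) {
    cluster_geometry(clusters)
  } else {
    NULL
  }

  # --- rearrangement scan ---
  rearr <- detect_rearrangements(
    lg[, c("chrom", "pos", "group")],
    data.frame(group = group_rows$group,
               primary_chromosome = group_rows$primary_chromosome),
    sim$targets)
  restricted <- rearr[rearr$restricted, , drop = FALSE]
  perm <- NULL; obs <- NULL
  if (nrow(restricted) > 0L) {
    # targeted regions containing at least one LG SNP within 1 kb
    n_regions <- sum(vapply(seq_len(nrow(sim$targets)), function(i) {
      any(lg$chrom == sim$targets$chrom[i] &
            lg$pos >= sim$targets$start[i] - 1000 &
            lg$pos <= sim$targets$end[i] + 1000)
    }, logical(1)))
    obs <- observed_clustering(restricted$nearest_target)
    perm <- permutation_clustering_test(nrow(restricted),
                                        max(n_regions, 1L),
                                        reps = perm_reps)
  }

  table1 <- if (!is.null(region_calls) && nrow(region_calls) > 0L) {
    make_table1(region_calls, clusters)
  } else {
    NULL
  }

  list(calls = state_mat, lg_snps = lg, biparental = snp_sel$biparental,
       maps = maps, groups = group_rows, markers = mk, matrices = mats,
       trees = trees, labels = labels, region_calls = region_calls,
       clusters = clusters,
       tests = list(excess = excess, direction = direction,
                    geometry = geometry),
       rearrangements = list(events = rearr, observed = obs,
                             permutation = perm),
       table1 = table1, log = log)
}

#' Simulate and analyze in one call
#'
#' Convenience wrapper: runs [simulate_octoploid_experiment()] followed by
#' [analyze_experiment()], optionally writing the report bundle (LG SNP
#' table, map table, PHYLIP matrices, region-count table, cluster and
#' rearrangement tables, decision log) as tab-separated files.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory for the report bundle.
#' @param ... passed to [analyze_experiment()].
#' @return list with `sim` and `analysis`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL, ...) {
  sim <- simulate_octoploid_experiment(config)
  analysis <- analyze_experiment(sim, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) {
      if (!is.null(x)) {
        df <- as.data.frame(x)
        listcols <- vapply(df, is.list, logical(1))
        for (lc in which(listcols)) {
          df[[lc]] <- vapply(df[[lc]], function(v) {
            paste(unlist(v), collapse = ",")
          }, character(1))
        }
        utils::write.table(df, file.path(out_dir, f), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    wt(analysis$lg_snps, "lg_snps.tsv")
    wt(analysis$groups, "linkage_groups.tsv")
    wt(analysis$region_calls, "region_calls.tsv")
    wt(analysis$clusters, "clusters.tsv")
    wt(analysis$rearrangements$events, "rearrangements.tsv")
    wt(analysis$table1, "region_counts.tsv")
    for (ch in names(analysis$matrices)) {
      write_phylip_matrix(analysis$matrices[[ch]],
                          file.path(out_dir, paste0("matrix_", ch, ".phy")))
    }
    writeLines(analysis$log, file.path(out_dir, "decision_log.txt"))
  }
  list(sim = sim, analysis = analysis)
}
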
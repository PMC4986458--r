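#' Two-point recombination fraction and LOD for a testcross pair
#'
#' Both markers segregate 1:1 (HET x HOM testcross configuration), coded
#' 1 = heterozygous, 0 = homozygous, NA = missing. Linkage phase is unknown,
#' so the phase minimising the recombination fraction is chosen: with
#' `k` = matches under the better phase out of `n` pairwise-complete
#' progeny, `rf = (n - k) / n` (clamped to `[1e-6, 0.5]`) and
#' `LOD = k log10(2 (1 - rf)) + (n - k) log10(2 rf)`.
#'
#' @param v1,v2 integer/logical vectors of per-progeny states (1/0/NA).
#' @return list with `rf`, `lod`, `n` (pairwise-complete progeny). `NULL`
#'   when no complete pairs exist.
#' @export
two_point_rf_lod <- function(v1, v2) {
  ok <- !is.na(v1) & !is.na(v2)
  n <- sum(ok)
  if (n == 0L) return(NULL)
  same <- sum(v1[ok] == v2[ok])
  k <- max(same, n - same)          # phase minimising rf
  rf <- min(max((n - k) / n, 1e-6), 0.5)
  lod <- k * log10(2 * (1 - rf)) + (n - k) * log10(2 * rf)
  list(rf = rf, lod = lod, n = n)
}

#' All pairwise two-point statistics within one parent
#'
#' Vectorised version of [two_point_rf_lod()] over a marker-by-progeny
#' segregation matrix (1/0/NA), with pairwise deletion of missing
#' genotypes.
#'
#' @param seg integer matrix markers x progeny.
#' @return list of matrices `rf`, `lod`, `n` (markers x markers; diagonal
#'   rf 0). Pairs with no complete progeny get `n = 0`, `lod = -Inf`.
#' @export
pairwise_rf_lod <- function(seg) {
  seg <- as.matrix(seg)
  m1 <- (seg == 1L); m1[is.na(m1)] <- FALSE
  m0 <- (seg == 0L); m0[is.na(m0)] <- FALSE
  m1 <- m1 * 1; m0 <- m0 * 1
  same <- m1 %*% t(m1) + m0 %*% t(m0)
  diff <- m1 %*% t(m0) + m0 %*% t(m1)
  n <- same + diff
  k <- pmax(same, diff)
  rf <- (n - k) / pmax(n, 1L)
  rf <- pmin(pmax(rf, 1e-6), 0.5)
  lod <- k * log10(2 * (1 - rf)) + (n - k) * log10(2 * rf)
  lod[n == 0] <- -Inf
  diag(rf) <- 0; diag(lod) <- Inf; diag(lod)[rowSums(n) == 0] <- -Inf
  rownames(rf) <- colnames(rf) <- rownames(seg)
  rownames(lod) <- colnames(lod) <- rownames(seg)
  rownames(n) <- colnames(n) <- rownames(seg)
  list(rf = rf, lod = lod, n = n)
}

#' Group markers by single-linkage transitive closure at a LOD threshold
#'
#' Markers joined by any chain of pairwise LOD >= `threshold` edges fall in
#' one linkage group. Output is independent of marker input order (groups
#' are renumbered by their smallest member index).
#'
#' @param lod symmetric LOD matrix (as from [pairwise_rf_lod()]).
#' @param threshold grouping LOD (default 5).
#' @return integer vector of group ids, one per marker.
#' @export
cluster_at_lod <- function(lod, threshold = 5) {
  m <- nrow(lod)
  adj <- (lod >= threshold)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # stable ids: renumber by first occurrence
  as.integer(factor(comp, levels = unique(comp)))
}

#' Kosambi and Haldane map functions
#'
#' Convert a recombination fraction to centimorgans. Kosambi:
#' `d = 25 ln((1 + 2r) / (1 - 2r))`; Haldane: `d = -50 ln(1 - 2r)`.
#' Both are monotone increasing on `[0, 0.5)` and diverge as `r -> 0.5`.
#'
#' @param r recombination fraction in `[0, 0.5)`.
#' @return distance in cM.
#' @export
kosambi_cm <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

#' @rdname kosambi_cm
#' @export
haldane_cm <- function(r) -50 * log(1 - 2 * r)

#' Order markers within a group and split at large gaps
#'
#' Markers are ordered by greedy nearest-neighbour seriation on the
#' recombination-fraction matrix: the chain starts at the marker with the
#' largest mean rf to the others (an end of the group) and repeatedly
#' appends the unplaced marker closest to the current end, breaking ties by
#' reference position. Adjacent rf values are converted to cM with the
#' chosen map function and the chain is cut wherever an adjacent gap
#' exceeds `gap_cM`.
#'
#' @param rf recombination-fraction matrix for the group's markers.
#' @param positions reference positions used for tie-breaking (and for
#'   deterministic chain starts).
#' @param gap_cM split threshold in centimorgans (default 33).
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @return list with `order` (permutation of marker indices), `cm`
#'   (cumulative cM along the chain) and `piece` (integer split-piece id
#'   per ordered marker).
#' @export
order_and_split <- function(rf, positions, gap_cM = 33,
                            map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  to_cm <- if (map_function == "kosambi") kosambi_cm else haldane_cm
  m <- nrow(rf)
  if (m == 1L) {
    return(list(order = 1L, cm = 0, piece = 1L))
  }
  mean_rf <- rowMeans(rf)
  start <- which(mean_rf == max(mean_rf))
  start <- start[order(positions[start])][1L]
  placed <- start
  remaining <- setdiff(seq_len(m), start)
  while (length(remaining) > 0L) {
    d <- rf[placed[length(placed)], remaining]
    nxt <- remaining[d == min(d)]
    nxt <- nxt[order(positions[nxt])][1L]
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  steps <- vapply(seq_len(m - 1L), function(i) {
    to_cm(min(rf[placed[i], placed[i + 1L]], 0.5 - 1e-9))
  }, numeric(1))
  piece <- c(1L, cumsum(steps > gap_cM) + 1L)
  cm <- c(0, cumsum(steps))
  # restart cM at 0 within each split piece
  for (p in unique(piece)) cm[piece == p] <- cm[piece == p] - min(cm[piece == p])
  list(order = placed, cm = cm, piece = piece)
}

#' Primary reference chromosome of a linkage group
#'
#' The chromosome carrying the majority of the group's markers. Ties go to
#' the lexicographically smallest chromosome id (natural order for
#' identically prefixed names) and are flagged.
#'
#' @param chroms reference chromosome per member marker.
#' @return list with `chromosome` and logical `tie`.
#' @export
assign_primary_chromosome <- function(chroms) {
  if (length(chroms) == 0L) stop("empty linkage group")
  tab <- table(chroms)
  top <- names(tab)[tab == max(tab)]
  tie <- length(top) > 1L
  if (tie) {
    warning("primary-chromosome tie between ",
            paste(sort(top), collapse = ", "),
            "; taking the smaller index")
  }
  list(chromosome = sort(top)[1L], tie = tie)
}

#' Pair maternal and paternal linkage groups through biparental SNP regions
#'
#' SNPs heterozygous in both parents are never mapped, but their regions
#' can be covered by one maternal and one paternal group; the number of
#' shared biparental regions weights a bipartite graph and a maximum-weight
#' matching pairs the groups.
#'
#' @param weights numeric matrix, maternal groups x paternal groups; entry
#'   = count of biparental SNP regions shared by the pair. Dimnames label
#'   the groups.
#' @return data.frame with columns `maternal`, `paternal`, `weight` (only
#'   matched pairs with positive weight).
#' @export
pair_parental_groups <- function(weights) {
  weights <- as.matrix(weights)
  nm <- nrow(weights); np <- ncol(weights)
  mlab <- rownames(weights); plab <- colnames(weights)
  if (is.null(mlab)) mlab <- paste0("m", seq_len(nm))
  if (is.null(plab)) plab <- paste0("p", seq_len(np))
  idx <- which(weights > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(maternal = character(0), paternal = character(0),
                      weight = numeric(0)))
  }
  edges <- as.vector(t(cbind(idx[, 1L], nm + idx[, 2L])))
  g <- igraph::make_bipartite_graph(c(rep(0, nm), rep(1, np)), edges,
                                    directed = FALSE)
  w <- weights[idx]
  match <- igraph::max_bipartite_match(g, weights = w)$matching
  out <- data.frame(maternal = character(0), paternal = character(0),
                    weight = numeric(0))
  for (i in seq_len(nm)) {
    j <- match[i]
    if (!is.na(j)) {
      out <- rbind(out, data.frame(maternal = mlab[i],
                                   paternal = plab[j - nm],
                                   weight = weights[i, j - nm]))
    }
  }
  out
}

#' Compose a linkage-group name
#'
#' Hyphen-joined `Species-Numeral-Subgenome-parent`, e.g.
#' `"Fvirg-IV-Av-p"`: species code, haploid chromosome as a Roman numeral
#' (I through VII), phylogenetic subgenome label (`Av`, `B1`, `B2`, `Bi`)
#' and parent (`m` maternal, `p` paternal).
#'
#' @param species species code string.
#' @param numeral Roman numeral I..VII.
#' @param subgenome one of `Av`, `B1`, `B2`, `Bi`.
#' @param parent `"m"` or `"p"`.
#' @return name string.
#' @export
name_group <- function(species, numeral, subgenome, parent) {
  if (!numeral %in% c("I", "II", "III", "IV", "V", "VI", "VII")) {
    stop("chromosome numeral must be I..VII, got ", numeral)
  }
  if (!subgenome %in% c("Av", "B1", "B2", "Bi")) {
    stop("invalid subgenome label: ", subgenome)
  }
  if (!parent %in% c("m", "p")) stop("parent must be 'm' or 'p'")
  paste(species, numeral, subgenome, parent, sep = "-")
}

#' Roman numeral for a haploid chromosome index 1..7
#' @param i integer 1..7.
#' @return Roman numeral string.
#' @export
chromosome_numeral <- function(i) {
  stopifnot(i >= 1, i <= 7)
  as.character(utils::as.roman(i))
}

#' Build linkage groups for one parent from LG SNP segregation data
#'
#' Runs the full grouping pass: pairwise two-point statistics, LOD
#' clustering, nearest-neighbour ordering with gap splitting, rejoining of
#' split pieces that share a primary reference chromosome (a deterministic
#' stand-in for manual curation; every join is logged), and major/minor
#' classification.
#'
#' @param seg segregation matrix markers x progeny (1/0/NA), rownames =
#'   marker ids.
#' @param chrom,pos reference chromosome and position per marker.
#' @param lod_threshold grouping LOD (default 5).
#' @param gap_cM split threshold (default 33).
#' @param min_major minimum LG SNPs for a "major" group (default 5).
#' @param map_function map function passed to [order_and_split()].
#' @param rejoin logical: rejoin split/parallel groups sharing a primary
#'   chromosome when each piece's markers fall on the same chromosome
#'   (default TRUE).
#' @return list with `markers` (data.frame: marker, chrom, pos, group, cm),
#'   `groups` (data.frame: group, n_markers, primary_chromosome, tie,
#'   major) and `log` (character vector of automatic decisions).
#' @export
build_linkage_groups <- function(seg, chrom, pos, lod_threshold = 5,
                                 gap_cM = 33, min_major = 5,
                                 map_function = "kosambi", rejoin = TRUE) {
  seg <- as.matrix(seg)
  m <- nrow(seg)
  ids <- rownames(seg)
  if (is.null(ids)) ids <- paste0("M", seq_len(m))
  pw <- pairwise_rf_lod(seg)
  grp0 <- cluster_at_lod(pw$lod, threshold = lod_threshold)
  log <- sprintf("LOD %.3g clustering: %d initial groups", lod_threshold,
                 length(unique(grp0)))
  piece_id <- integer(m)
  cm <- numeric(m)
  next_id <- 0L
  for (g in unique(grp0)) {
    members <- which(grp0 == g)
    os <- order_and_split(pw$rf[members, members, drop = FALSE],
                          pos[members], gap_cM = gap_cM,
                          map_function = map_function)
    ordered <- members[os$order]
    for (p in unique(os$piece)) {
      next_id <- next_id + 1L
      sel <- ordered[os$piece == p]
      piece_id[sel] <- next_id
      cm[sel] <- os$cm[os$piece == p]
      if (p > 1L) {
        log <- c(log, sprintf(
          "split: group %d piece %d separated at gap > %g cM", g, p, gap_cM))
      }
    }
  }
  if (rejoin) {
    # rejoin pieces whose primary chromosome agrees (logged)
    prim <- vapply(seq_len(next_id), function(p) {
      assign_primary_chromosome(chrom[piece_id == p])$chromosome
    }, character(1))
    for (ch in unique(prim)) {
      pieces <- which(prim == ch)
      if (length(pieces) > 1L) {
        # only join pieces that came from the same LOD cluster (splits),
        # keeping independent homeologous groups apart
        src <- vapply(pieces, function(p) grp0[piece_id == p][1L], integer(1))
        for (s in unique(src)) {
          same <- pieces[src == s]
          if (length(same) > 1L) {
            keep <- same[1L]
            for (p in same[-1L]) {
              # restack the joined piece's cM after the kept piece
              offset <- max(cm[piece_id == keep]) + gap_cM
              cm[piece_id == p] <- cm[piece_id == p] + offset
              piece_id[piece_id == p] <- keep
              log <- c(log, sprintf(
                "join: pieces %d+%d rejoined (both primary %s, same LOD cluster)",
                keep, p, ch))
            }
          }
        }
      }
    }
  }
  group <- as.integer(factor(piece_id, levels = unique(piece_id)))
  groups <- do.call(rbind, lapply(sort(unique(group)), function(g) {
    members <- group == g
    pc <- suppressWarnings(assign_primary_chromosome(chrom[members]))
    data.frame(group = g, n_markers = sum(members),
               primary_chromosome = pc$chromosome, tie = pc$tie,
               major = sum(members) >= min_major)
  }))
  markers <- data.frame(marker = ids, chrom = chrom, pos = pos,
                        group = group, cm = cm, stringsAsFactors = FALSE)
  list(markers = markers, groups = groups, log = log)
}
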
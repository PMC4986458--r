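#' Order and orient scaffolds into pseudochromosomes from linkage anchors
#'
#' Scaffolds are placed on the chromosome of their linkage group and
#' ordered by the median cM of their anchors; the prior (existing
#' assembly) order is kept wherever the maps provide no evidence:
#' unanchored scaffolds keep their prior slot, and only the anchored
#' subset is stably reordered among the slots it occupied. A scaffold with
#' two or more anchors whose scaffold-coordinate order is anticorrelated
#' with cM is flipped; single-anchor scaffolds keep the prior (forward)
#' orientation. A scaffold anchored to two different linkage groups is a
#' split candidate and is divided at the midpoint between the two
#' conflicting anchors, both halves being placed independently (each
#' split is logged). Placed scaffolds are separated by fixed `gap`-bp
#' runs of `N`.
#'
#' @param scaffolds named integer vector of scaffold lengths.
#' @param anchors data.frame with columns `scaffold`, `scaffold_pos`,
#'   `group` (linkage group id), `cm`.
#' @param group_chromosome named vector mapping linkage group ->
#'   chromosome name.
#' @param prior data.frame with columns `scaffold`, `chrom`, `rank`
#'   (prior order within chromosome); every scaffold must appear.
#' @param gap inter-scaffold gap in bp (default 10000).
#' @return list with `layout` (data.frame: `chrom`, `start`, `end`,
#'   `scaffold`, `orientation`, `anchored`) and `log` (split/flip
#'   messages). Coordinates are 1-based; gaps are implicit between rows.
#' @export
order_scaffolds <- function(scaffolds, anchors, group_chromosome, prior,
                            gap = 10000) {
  if (!all(anchors$scaffold %in% names(scaffolds))) {
    stop("anchor references unknown scaffold: ",
         setdiff(anchors$scaffold, names(scaffolds))[1L])
  }
  log <- character(0)
  # split candidates: anchors on >1 linkage group
  lens <- scaffolds
  anch <- anchors
  pri <- prior
  for (sc in unique(anchors$scaffold)) {
    a <- anch[anch$scaffold == sc, , drop = FALSE]
    if (length(unique(a$group)) > 1L) {
      a <- a[order(a$scaffold_pos), ]
      brk <- which(a$group[-1L] != a$group[-nrow(a)])[1L]
      mid <- floor((a$scaffold_pos[brk] + a$scaffold_pos[brk + 1L]) / 2)
      l <- lens[[sc]]
      n1 <- paste0(sc, "_A"); n2 <- paste0(sc, "_B")
      lens <- lens[names(lens) != sc]
      lens[n1] <- mid; lens[n2] <- l - mid
      anch$scaffold[anch$scaffold == sc & anch$scaffold_pos <= mid] <- n1
      sel2 <- anch$scaffold == sc
      anch$scaffold_pos[sel2] <- anch$scaffold_pos[sel2] - mid
      anch$scaffold[sel2] <- n2
      pr <- pri[pri$scaffold == sc, ]
      pri <- pri[pri$scaffold != sc, ]
      pri <- rbind(pri,
                   data.frame(scaffold = c(n1, n2), chrom = pr$chrom,
                              rank = c(pr$rank, pr$rank + 0.5)))
      log <- c(log, sprintf(
        "split: scaffold %s divided at %d between groups %s and %s",
        sc, mid, a$group[brk], a$group[brk + 1L]))
    }
  }
  # per-scaffold placement evidence
  info <- do.call(rbind, lapply(names(lens), function(sc) {
    a <- anch[anch$scaffold == sc, , drop = FALSE]
    p <- pri[pri$scaffold == sc, , drop = FALSE]
    if (nrow(a) == 0L) {
      return(data.frame(scaffold = sc, chrom = p$chrom[1L],
                        rank = p$rank[1L], anchored = FALSE,
                        cm = NA_real_, orientation = "+"))
    }
    grp <- names(sort(table(a$group), decreasing = TRUE))[1L]
    ori <- "+"
    if (nrow(a) >= 2L &&
        stats::cor(a$scaffold_pos, a$cm, method = "spearman") < 0) {
      ori <- "-"
      log <<- c(log, sprintf("flip: scaffold %s anticorrelated with cM", sc))
    }
    data.frame(scaffold = sc,
               chrom = unname(group_chromosome[[as.character(grp)]]),
               rank = p$rank[1L], anchored = TRUE,
               cm = stats::median(a$cm), orientation = ori)
  }))
  layout <- NULL
  for (ch in unique(info$chrom)) {
    d <- info[info$chrom == ch, , drop = FALSE]
    d <- d[order(d$rank), ]
    slots <- which(d$anchored)
    if (length(slots) > 1L) {
      # stable reorder of the anchored subset by median cM (prior-rank ties)
      anchored <- d[slots, , drop = FALSE]
      anchored <- anchored[order(anchored$cm, anchored$rank), ]
      d[slots, ] <- anchored
    }
    pos <- 1L
    for (i in seq_len(nrow(d))) {
      layout <- rbind(layout, data.frame(
        chrom = ch, start = pos, end = pos + lens[[d$scaffold[i]]] - 1L,
        scaffold = d$scaffold[i], orientation = d$orientation[i],
        anchored = d$anchored[i], stringsAsFactors = FALSE))
      pos <- pos + lens[[d$scaffold[i]]] + gap
    }
  }
  rownames(layout) <- NULL
  list(layout = layout, log = log)
}

#' Total pseudochromosome lengths implied by a layout
#'
#' @param layout data.frame from [order_scaffolds()].
#' @return named numeric vector of pseudochromosome lengths (scaffolds plus
#'   gaps).
#' @export
pseudochromosome_lengths <- function(layout) {
  vapply(split(layout, layout$chrom), function(d) max(d$end), numeric(1))
}

#' Count stretches of continuously syntenous genes
#'
#' Given orthologs ordered along the focal assembly, each carrying the
#' chromosome of its partner-genome ortholog, counts maximal runs of
#' identical partner-chromosome labels. Local order shuffling within a run
#' does not break it; only a change of partner chromosome does, so the
#' count equals one plus the number of label changes.
#'
#' @param partner_chromosomes vector of partner-genome chromosome labels
#'   in focal-assembly order.
#' @return integer stretch count (0 for empty input).
#' @export
count_synteny_stretches <- function(partner_chromosomes) {
  if (length(partner_chromosomes) == 0L) return(0L)
  length(rle(as.vector(partner_chromosomes))$lengths)
}
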
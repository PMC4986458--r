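# Shared fixtures. The heavy end-to-end simulation is computed once per
# test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

# Desk-scale study configuration used by the end-to-end tests: two
# chromosomes keep the runtime modest while target density, progeny count
# and depth keep marker density representative (see the methods vignette).
endtoend_config <- function() {
  sim_config(seed = 11, n_chromosomes = 2, chromosome_length = 120000,
             targets_per_chromosome = 70, n_progeny = 42, depth = 70,
             error_rate = 0, het_rate = 0.004,
             recomb_per_chromosome = 0.5,
             n_tracts = 4, tract_length = 8000, n_transpositions = 2)
}

endtoend_fixture <- function() {
  if (is.null(.fixture_env$endtoend)) {
    cfg <- endtoend_config()
    sim <- simulate_octoploid_experiment(cfg)
    an <- analyze_experiment(sim, perm_reps = 200)
    .fixture_env$endtoend <- list(cfg = cfg, sim = sim, an = an)
  }
  .fixture_env$endtoend
}

# Truth keys for planted parental het sites
planted_keys <- function(sim) {
  truth <- sim$truth$het_sites
  paste(truth$parent, truth$chrom, truth$pos)
}

# Planted het sites that are genuinely single-subgenome heterozygous and
# observable: inside a capture window, not coinciding with another
# injected het, and not coinciding with a fixed lineage variant (such
# sites are multi-allelic or non-1/8 and are correctly rejected by the
# Mendelian filters).
planted_clean <- function(sim) {
  truth <- sim$truth$het_sites
  cfg <- sim$config
  inwin <- vapply(seq_len(nrow(truth)), function(i) {
    tg <- sim$targets[sim$targets$chrom == truth$chrom[i], ]
    any(abs(tg$central - truth$pos[i]) < cfg$read_length)
  }, logical(1))
  key_pos <- paste(truth$chrom, truth$pos)
  dup <- key_pos %in% key_pos[duplicated(key_pos)]
  fixed <- unlist(lapply(sim$lineages$chrom_names, function(ch) {
    pos <- integer(0)
    for (tx in sim$lineages$taxa) pos <- c(pos, tx[[ch]]$pos)
    for (sg in sim$lineages$subgenomes) pos <- c(pos, sg[[ch]]$pos)
    paste(ch, unique(pos))
  }))
  inwin & !dup & !(key_pos %in% fixed)
}

# True subgenome per linkage group: modal planted subgenome of the
# group's member LG SNPs.
group_truth_labels <- function(sim, an) {
  truth <- sim$truth$het_sites
  tk <- paste(truth$parent, truth$chrom, truth$pos)
  lk <- paste(an$lg_snps$parent, an$lg_snps$chrom, an$lg_snps$pos)
  true_sg <- truth$subgenome[match(lk, tk)]
  tapply(true_sg, an$lg_snps$group, function(x) {
    tb <- table(x)
    if (length(tb) == 0L) NA_character_ else names(sort(tb,
                                                        decreasing = TRUE))[1L]
  })
}

# Independent hand-rule oracle for the octoploid caller (thresholds as
# unit fractions: 2.5% = 1/40, 1.25% = 1/80; integer cross-multiplication)
oracle_octoploid_call <- function(counts, min_depth = 32) {
  counts <- counts[c("A", "C", "G", "T")]
  depth <- sum(counts)
  if (depth < min_depth) return("MISSING")
  srt <- sort(counts, decreasing = TRUE)
  mc <- srt[2L]
  if (mc > 0 && srt[3L] == mc) return("MISSING")  # non-biallelic tie
  if (mc == 0) return("HOM")
  if (mc >= 2 && mc * 40 >= depth) return("HET")
  if (mc == 1 && mc * 80 < depth) return("HOM")
  "MISSING"
}

# Exhaustive least-squares topology scorer: the NJ oracle for <= 6 taxa.
# Path-indicator regression of pairwise distances on edges, per topology.
ls_best_topology <- function(d) {
  taxa <- rownames(d)
  topos <- phangorn::allTrees(length(taxa), rooted = FALSE,
                              tip.label = taxa)
  rss <- vapply(topos, function(tr) {
    X <- path_matrix(tr)
    y <- d[t(utils::combn(taxa, 2))]
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  topos[[which.min(rss)]]
}

# pair x edge indicator matrix for a tree
path_matrix <- function(tr) {
  taxa <- tr$tip.label
  pairs <- utils::combn(taxa, 2)
  n_edge <- nrow(tr$edge)
  X <- matrix(0, ncol(pairs), n_edge)
  clades <- lapply(seq_len(n_edge), function(e) {
    node <- tr$edge[e, 2L]
    if (node <= length(taxa)) taxa[node] else
      ape::extract.clade(tr, node)$tip.label
  })
  for (k in seq_len(ncol(pairs))) {
    for (e in seq_len(n_edge)) {
      X[k, e] <- xor(pairs[1L, k] %in% clades[[e]],
                     pairs[2L, k] %in% clades[[e]])
    }
  }
  X
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1L] == 0
}

# evolve equal-rate sequences along an ape tree (edge length = per-site
# substitution probability); returns a taxa x sites character matrix
.sim_seq_on_tree <- function(tree, n_sites = 2000) {
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- sample(bases, n_sites, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(ord))) {
    parent <- ord[e, 1L]; child <- ord[e, 2L]
    s <- seqs[[parent]]
    mut <- which(stats::runif(n_sites) < min(lens[e], 0.45))
    if (length(mut) > 0) {
      s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1L),
                       character(1))
    }
    seqs[[child]] <- s
  }
  out <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(out) <- tree$tip.label
  out
}

# random region-call track for the cluster-detection oracle
random_track <- function(n, seed = NULL) {
  classes <- c("INTROGRESSION_LIKE", "SUPPORTIVE", "OUTGROUP",
               "SUPPORT_HOMOPLASY")
  cls <- sample(classes, n, replace = TRUE,
                prob = c(0.4, 0.3, 0.15, 0.15))
  starts <- cumsum(sample(500:3000, n, replace = TRUE))
  data.frame(class = cls, start = starts, end = starts + 200,
             maps = I(as.list(rep("m", n))))
}
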
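small_cfg <- function(...) {
  sim_config(seed = 5, n_chromosomes = 1, chromosome_length = 30000,
             targets_per_chromosome = 20, n_progeny = 20, depth = 50,
             error_rate = 0, het_rate = 0.003, n_tracts = 1,
             tract_length = 5000, n_transpositions = 0, ...)
}

test_that("generators are seed-deterministic", {
  cfg <- small_cfg()
  s1 <- simulate_octoploid_experiment(cfg, reads = FALSE)
  s2 <- simulate_octoploid_experiment(cfg, reads = FALSE)
  expect_identical(s1$lineages$reference, s2$lineages$reference)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$het_sites, s2$truth$het_sites)
})

test_that("zero rates produce identical lineage sequences", {
  cfg <- small_cfg()
  cfg$rates <- list(outgroup = 0, vesca_clade = 0, b_clade = 0,
                    bi_clade = 0, tip = 0, tip_b1 = 0)
  cfg$n_tracts <- 0
  set.seed(1)
  lin <- simulate_lineages(cfg)
  for (tx in lin$taxa) expect_equal(length(tx[["chr1"]]$pos), 0L)
  for (sg in lin$subgenomes) expect_equal(length(sg[["chr1"]]$pos), 0L)
})

test_that("branch substitution counts scale with rate and length", {
  cfg <- small_cfg()
  set.seed(2)
  counts <- replicate(30, {
    lin <- simulate_lineages(cfg)
    length(lin$taxa$outgroup[["chr1"]]$pos)
  })
  expected <- cfg$chromosome_length * cfg$rates$outgroup
  expect_equal(mean(counts), expected, tolerance = 0.05)
})

test_that("planted tracts copy the vesca lineage into the target subgenome", {
  cfg <- small_cfg()
  set.seed(3)
  lin <- simulate_lineages(cfg)
  tr <- lin$tracts[1, ]
  pos <- seq(tr$start, tr$end, by = 7)
  expect_equal(subgenome_base(lin, tr$subgenome, rep(tr$chrom,
                                                     length(pos)), pos),
               taxon_base(lin, "vesca", rep(tr$chrom, length(pos)), pos))
  expect_true(tr$subgenome %in% c("Bi", "B1", "B2"))  # default direction
})

test_that("zero recombination transmits intact parental haplotypes", {
  cfg <- small_cfg()
  cfg$recomb_per_chromosome <- 0
  set.seed(4)
  gam <- homeolink:::.make_gamete(cfg$chromosome_length, 0)
  expect_equal(length(gam$breaks), 0L)
  hap_pair <- list(homeolink:::.vm(c(10L, 20L), c("A", "C")),
                   homeolink:::.vm(c(10L, 30L), c("G", "T")))
  vm <- homeolink:::.gamete_vm(hap_pair, gam, cfg$chromosome_length)
  expect_identical(vm, hap_pair[[gam$start_hap]])
})

test_that("a single-parent het site segregates ~1:1 and at ~1/8 frequency", {
  cfg <- small_cfg()
  cfg$het_rate <- 0.004
  sim <- simulate_octoploid_experiment(cfg, reads = FALSE)
  truth <- sim$truth$het_sites
  keep <- planted_clean(sim)
  expect_gt(sum(keep), 10)
  truth <- truth[keep, ][1:10, ]
  cn <- sim$counts
  frac_het <- numeric(0)
  minor_freq <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    cc <- cn[cn$chrom == truth$chrom[i] & cn$pos == truth$pos[i], ]
    par_row <- cc[cc$sample == truth$parent[i], ]
    minor_freq <- c(minor_freq,
                    par_row[[truth$base[i]]] / par_row$depth)
    prog <- cc[grepl("^F1_", cc$sample), ]
    carrier <- prog[[truth$base[i]]] >= 2
    frac_het <- c(frac_het, mean(carrier))
  }
  # carrier parent shows the minor allele near 1/8 frequency
  expect_equal(mean(minor_freq), 1 / 8, tolerance = 0.2)
  # progeny inherit the het allele in about half of individuals
  expect_equal(mean(frac_het), 0.5, tolerance = 0.15)
})

test_that("at zero error and adequate depth the carrier parent calls HET", {
  cfg <- small_cfg()
  sim <- simulate_octoploid_experiment(cfg, reads = FALSE)
  truth <- sim$truth$het_sites[planted_clean(sim), ]
  cn <- sim$counts
  ok <- logical(0)
  for (i in seq_len(nrow(truth))) {
    row <- cn[cn$chrom == truth$chrom[i] & cn$pos == truth$pos[i] &
                cn$sample == truth$parent[i], ]
    gc <- call_octoploid_genotype(unlist(row[c("A", "C", "G", "T")]))
    # HET whenever the evidence exists: depth adequate and the variant
    # allele sampled at least twice (one haplotype in eight)
    sampled <- row[[truth$base[i]]] >= 2
    ok <- c(ok, gc$state == "HET" || row$depth < 32 || !sampled)
  }
  expect_true(all(ok))
})

test_that("capture reads cover the target and carry haplotype variants", {
  cfg <- small_cfg()
  cfg$targets_per_chromosome <- 5
  cfg$n_progeny <- 16
  sim <- simulate_octoploid_experiment(cfg, reads = TRUE)
  rd <- sim$reads
  expect_gt(nrow(rd), 0)
  expect_true(all(nchar(rd$seq) <= cfg$read_length))
  # every read overlaps a target centre
  ctr <- sim$targets$central
  covers <- vapply(seq_len(nrow(rd)), function(i) {
    any(sim$targets$chrom == rd$chrom[i] & ctr >= rd$start[i] &
          ctr <= rd$start[i] + nchar(rd$seq[i]) - 1L)
  }, logical(1))
  expect_true(all(covers))
  # read pileups at het sites reflect the variant allele (about 1 read
  # in 8 from the carrier parent); aggregate over sites near the centres
  truth <- sim$truth$het_sites[planted_clean(sim), ]
  near <- vapply(seq_len(nrow(truth)), function(i) {
    tg <- sim$targets[sim$targets$chrom == truth$chrom[i], ]
    any(abs(tg$central - truth$pos[i]) < 30)
  }, logical(1))
  truth <- truth[near, , drop = FALSE]
  expect_gt(nrow(truth), 0)
  carriers <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    pr <- rd[rd$sample == tr$parent & rd$chrom == tr$chrom &
               rd$start <= tr$pos &
               rd$start + nchar(rd$seq) - 1L >= tr$pos, ]
    bases <- substr(pr$seq, tr$pos - pr$start + 1L, tr$pos - pr$start + 1L)
    carriers <- carriers + sum(bases == tr$base)
  }
  expect_gt(carriers, 0)
})

test_that("simulated counts round-trip through mpileup text", {
  cfg <- small_cfg()
  cfg$targets_per_chromosome <- 3
  cfg$n_progeny <- 16
  sim <- simulate_octoploid_experiment(cfg, reads = FALSE)
  sub <- sim$counts[sim$counts$sample %in% c("maternal", "paternal"), ]
  sub <- sub[sub$pos %in% unique(sub$pos)[1:20], ]
  tf <- withr::local_tempfile()
  write_pileup(sub, tf, c("maternal", "paternal"))
  back <- read_pileup(tf, c("maternal", "paternal"))
  key <- function(d) paste(d$chrom, d$pos, d$sample)
  sub <- sub[order(key(sub)), ]
  back <- back[order(key(back)), ]
  expect_equal(back[, c("A", "C", "G", "T")],
               sub[, c("A", "C", "G", "T")], ignore_attr = TRUE)
})
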
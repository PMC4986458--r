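test_that("octoploid caller applies the stated thresholds", {
  expect_equal(call_octoploid_genotype(c(A = 78, C = 0, G = 0, T = 2))$state,
               "HET")  # 2 copies at exactly 2.5%
  expect_equal(call_octoploid_genotype(c(A = 78, C = 0, G = 0,
                                         T = 2))$minor_allele, "T")
  expect_equal(call_octoploid_genotype(c(A = 30, C = 0, G = 0, T = 1))$state,
               "MISSING")  # depth 31 < 32
  expect_equal(call_octoploid_genotype(c(A = 39, C = 0, G = 0, T = 1))$state,
               "MISSING")  # single copy at 2.5%: neither rule fires
  expect_equal(call_octoploid_genotype(c(A = 199, C = 0, G = 0, T = 1))$state,
               "HOM")  # single copy at 0.5% < 1.25%
  expect_equal(call_octoploid_genotype(c(A = 0, C = 0, G = 0, T = 0))$state,
               "MISSING")
  # two non-major alleles tied: not biallelic
  expect_equal(call_octoploid_genotype(c(A = 60, C = 3, G = 3, T = 0))$state,
               "MISSING")
})

test_that("caller matches the independent hand-rule oracle on random counts", {
  set.seed(42)
  for (rep in 1:500) {
    counts <- c(A = rpois(1, 50), C = rpois(1, 2), G = rpois(1, 0.5),
                T = rpois(1, 0.1))
    expect_equal(call_octoploid_genotype(counts)$state,
                 oracle_octoploid_call(counts), info = paste(counts,
                                                             collapse = ","))
  }
  # vectorised path agrees with the scalar path
  cm <- matrix(rpois(400, 15), ncol = 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  vec <- call_octoploid_genotypes(cm)
  for (i in seq_len(nrow(cm))) {
    expect_equal(vec$state[i], call_octoploid_genotype(cm[i, ])$state)
  }
})

test_that("caller is frequency-sensitive, not count-only", {
  # 10x rescaling preserves the call except where the >=2-copy rule binds
  base <- c(A = 199, C = 0, G = 0, T = 1)   # HOM at 0.5%
  expect_equal(call_octoploid_genotype(base)$state, "HOM")
  scaled <- base * 10                        # minor now 10 copies at 0.5%
  expect_equal(call_octoploid_genotype(scaled)$state, "MISSING")
  het <- c(A = 78, C = 0, G = 0, T = 2)
  expect_equal(call_octoploid_genotype(het * 10)$state,
               call_octoploid_genotype(het)$state)
})

test_that("LG SNP selection applies Mendelian and missingness filters", {
  mk_states <- function(n_het, n_hom, n_mis) {
    c(rep("HET", n_het), rep("HOM", n_hom), rep("MISSING", n_mis))
  }
  parent <- matrix(c("HET", "HOM",   # site 1: maternal only
                     "HOM", "HET",   # site 2: paternal only
                     "HET", "HET",   # site 3: biparental
                     "HET", "HOM"),  # site 4: maternal, fails progeny
                   ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("maternal", "paternal")))
  prog <- rbind(mk_states(20, 21, 1), mk_states(21, 21, 0),
                mk_states(20, 22, 0), mk_states(7, 35, 0))
  info <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L))
  res <- select_lg_snps(parent, prog, info)
  expect_equal(res$lg_snps$pos, c(100L, 200L))
  expect_equal(res$lg_snps$parent, c("maternal", "paternal"))
  expect_equal(res$biparental$pos, 300L)
  expect_equal(nchar(res$lg_snps$segregation[1]), 42L)
  # too few progeny is a configuration error
  expect_error(select_lg_snps(parent, prog[, 1:10], info),
               "at least 16")
})

test_that("LG SNP selection is invariant to progeny order", {
  set.seed(7)
  parent <- matrix(rep(c("HET", "HOM"), 5), ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("maternal", "paternal")))
  prog <- matrix(sample(c("HET", "HOM", "MISSING"), 5 * 42, replace = TRUE,
                        prob = c(0.48, 0.48, 0.04)), nrow = 5)
  info <- data.frame(chrom = "chr1", pos = 1:5 * 100L)
  a <- select_lg_snps(parent, prog, info)
  perm <- sample(42)
  b <- select_lg_snps(parent, prog[, perm], info)
  expect_equal(a$lg_snps$pos, b$lg_snps$pos)
  expect_equal(a$lg_snps$n_het, b$lg_snps$n_het)
})

test_that("diploid site filter enforces depth, PL and segregation rules", {
  # 2 parents + 41 offspring
  good_pl <- matrix(rep(c(0, 60, 200), 43), ncol = 3, byrow = TRUE)
  depths <- rep(30, 43)
  # individual with depth 19 -> missing
  d2 <- depths; d2[3] <- 19
  r <- filter_diploid_site(good_pl, d2)
  expect_true(is.na(r$genotype[3]))
  # PLs (0, 39, 200): second best < 40 -> missing
  pl2 <- good_pl; pl2[4, ] <- c(0, 39, 200)
  r2 <- filter_diploid_site(pl2, depths)
  expect_true(is.na(r2$genotype[4]))
  # all offspring the same genotype -> rejected (87.8% > 85%)
  pl3 <- good_pl
  pl3[1, ] <- c(200, 0, 60); pl3[2, ] <- c(200, 0, 60)  # het parents
  for (i in 8:12) pl3[i, ] <- c(200, 0, 60)
  # 36 of 41 offspring genotype 0, 5 genotype 1
  r3 <- filter_diploid_site(pl3, depths)
  expect_false(r3$retained)
  expect_match(r3$reason, "uniform")
  # balanced het x het segregation passes
  pl4 <- good_pl
  pl4[1, ] <- c(200, 0, 60); pl4[2, ] <- c(200, 0, 60)
  for (i in 3:22) pl4[i, ] <- c(200, 0, 60)
  for (i in 23:32) pl4[i, ] <- c(300, 80, 0)
  r4 <- filter_diploid_site(pl4, depths)
  expect_true(r4$retained)
  # non-Mendelian: HOM-ref x HOM-ref parents with het offspring
  pl5 <- good_pl
  for (i in 3:22) pl5[i, ] <- c(200, 0, 60)
  r5 <- filter_diploid_site(pl5, depths)
  expect_false(r5$retained)
})

test_that("1-kb region chaining matches the strict-inequality rule", {
  expect_equal(group_regions(c(1000, 1900, 3100)), c(1L, 1L, 2L))
  expect_equal(group_regions(c(500, 1500)), c(1L, 2L))  # exactly 1 kb apart
  expect_equal(group_regions(7), 1L)
  expect_equal(group_regions(integer(0)), integer(0))
  expect_error(group_regions(c(5, 1)), "sorted")
})

test_that("region assignment partitions positions with non-overlapping spans", {
  set.seed(3)
  for (rep in 1:20) {
    pos <- sort(sample.int(50000, 40))
    ids <- group_regions(pos)
    expect_equal(length(ids), length(pos))
    spans <- cbind(tapply(pos, ids, min), tapply(pos, ids, max))
    if (nrow(spans) > 1) {
      # regions ordered and separated by >= 1 kb
      expect_true(all(spans[-1, 1] - spans[-nrow(spans), 2] >= 1000))
    }
    # within-region adjacent gaps < 1 kb
    for (g in unique(ids)) {
      p <- pos[ids == g]
      if (length(p) > 1) expect_true(all(diff(p) < 1000))
    }
  }
})
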
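test_that("two-point rf/LOD matches the closed form at the extremes", {
  v <- rep(c(1L, 0L), 20)
  id <- two_point_rf_lod(v, v)
  expect_equal(id$n, 40)
  expect_equal(id$lod, 40 * log10(2), tolerance = 1e-4)
  expect_lt(id$rf, 1e-5)
  # complementary vectors: phase flip gives the same linkage
  comp <- two_point_rf_lod(v, 1L - v)
  expect_equal(comp$lod, id$lod)
  expect_equal(comp$rf, id$rf)
  # independent vectors: rf ~ 0.5, LOD ~ 0
  set.seed(1)
  a <- rbinom(2000, 1, 0.5); b <- rbinom(2000, 1, 0.5)
  ind <- two_point_rf_lod(a, b)
  expect_gt(ind$rf, 0.45)
  expect_lt(ind$lod, 1)
  expect_null(two_point_rf_lod(c(NA, NA), c(1L, 0L)))
})

test_that("pairwise matrix agrees with the scalar two-point statistic", {
  set.seed(5)
  seg <- matrix(sample(c(0L, 1L, NA), 8 * 30, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)), nrow = 8)
  pw <- pairwise_rf_lod(seg)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      ref <- two_point_rf_lod(seg[i, ], seg[j, ])
      if (is.null(ref)) {
        expect_equal(pw$n[i, j], 0)
      } else {
        expect_equal(pw$rf[i, j], ref$rf)
        expect_equal(pw$lod[i, j], ref$lod)
      }
    }
  }
})

test_that("LOD clustering is transitive and order-invariant", {
  lod <- matrix(0, 3, 3)
  lod[1, 2] <- lod[2, 1] <- 8
  lod[2, 3] <- lod[3, 2] <- 8
  lod[1, 3] <- lod[3, 1] <- 1
  diag(lod) <- Inf
  expect_equal(cluster_at_lod(lod), c(1L, 1L, 1L))
  # two independent blocks
  lod2 <- matrix(0, 4, 4); diag(lod2) <- Inf
  lod2[1, 2] <- lod2[2, 1] <- 9; lod2[3, 4] <- lod2[4, 3] <- 7
  expect_equal(cluster_at_lod(lod2), c(1L, 1L, 2L, 2L))
  # all below threshold -> singletons
  lod3 <- matrix(2, 3, 3); diag(lod3) <- Inf
  expect_equal(cluster_at_lod(lod3), 1:3)
  # permuting markers permutes but does not change the partition
  set.seed(2)
  m <- 12
  lodr <- matrix(runif(m * m, 0, 10), m, m)
  lodr <- (lodr + t(lodr)) / 2; diag(lodr) <- Inf
  g1 <- cluster_at_lod(lodr)
  perm <- sample(m)
  g2 <- cluster_at_lod(lodr[perm, perm])
  # same partition up to relabeling
  expect_equal(length(unique(g1)), length(unique(g2)))
  expect_true(all(tapply(g2, g1[perm], function(x) length(unique(x))) == 1))
})

test_that("Kosambi map function is monotone with known values", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.1), 25 * log(1.2 / 0.8))
  expect_equal(kosambi_cm(0.1), 10.14, tolerance = 1e-3)
  r <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(kosambi_cm(r)) > 0))
  expect_gt(kosambi_cm(0.4999), 100)
  expect_gt(haldane_cm(0.3), kosambi_cm(0.3))
})

test_that("ordering splits groups at large Kosambi gaps", {
  # three tight markers, then a near-independent fourth
  rf <- matrix(0.5 - 1e-4, 4, 4)
  rf[1:3, 1:3] <- 0.02
  diag(rf) <- 0
  os <- order_and_split(rf, positions = c(10, 20, 30, 5000))
  expect_equal(sort(unique(os$piece)), 1:2)
  # the isolated marker ends up alone in its piece
  expect_setequal(unname(table(os$piece)), c(1L, 3L))
  lone_piece <- names(which(table(os$piece) == 1))
  expect_equal(os$order[os$piece == as.integer(lone_piece)], 4L)
  # r = 0.1 between neighbours: ~10 cM gaps, no split
  rf2 <- matrix(0.1, 3, 3); diag(rf2) <- 0
  os2 <- order_and_split(rf2, positions = 1:3)
  expect_equal(unique(os2$piece), 1L)
  expect_equal(os2$cm[1], 0)
})

test_that("primary chromosome is the modal one, ties flagged to the smaller", {
  expect_equal(assign_primary_chromosome(
    c(rep("Fvb4", 30), rep("Fvb6", 2)))$chromosome, "Fvb4")
  expect_equal(assign_primary_chromosome("Fvb2")$chromosome, "Fvb2")
  expect_warning(r <- assign_primary_chromosome(rep(c("Fvb5", "Fvb3"), 5)),
                 "tie")
  expect_equal(r$chromosome, "Fvb3")
  expect_true(r$tie)
  expect_error(assign_primary_chromosome(character(0)), "empty")
})

test_that("parental-group pairing is a maximum-weight matching", {
  w <- matrix(0, 2, 3, dimnames = list(c("m1", "m2"),
                                       c("p1", "p2", "p3")))
  w["m1", "p3"] <- 1
  p <- pair_parental_groups(w)
  expect_equal(p$maternal, "m1")
  expect_equal(p$paternal, "p3")
  expect_equal(nrow(pair_parental_groups(matrix(0, 2, 2))), 0L)
  # greedy would err here if it paired m1-p2 first; brute force optimum
  # is (m1,p1), (m2,p2) with weight 9
  w2 <- matrix(c(5, 1, 0, 4), 2, 2, byrow = TRUE,
               dimnames = list(c("m1", "m2"), c("p1", "p2")))
  p2 <- pair_parental_groups(w2)
  expect_equal(sum(p2$weight), 9)
  # randomized cross-check against brute force over all matchings
  set.seed(9)
  for (rep in 1:20) {
    wr <- matrix(sample(0:6, 12, replace = TRUE), 3, 4)
    rownames(wr) <- paste0("m", 1:3); colnames(wr) <- paste0("p", 1:4)
    got <- sum(pair_parental_groups(wr)$weight)
    # brute force: every assignment of each maternal group to a paternal
    # group (1..4) or none (0), injective on the used paternal groups
    best <- 0
    idx <- expand.grid(0:4, 0:4, 0:4)
    for (k in seq_len(nrow(idx))) {
      a <- as.integer(idx[k, ])
      nz <- a[a > 0]
      if (anyDuplicated(nz)) next
      wsum <- sum(vapply(1:3, function(i) if (a[i] > 0) wr[i, a[i]] else 0,
                         numeric(1)))
      best <- max(best, wsum)
    }
    expect_equal(got, best)
  }
})

test_that("linkage-group names follow the Species-Numeral-Subgenome-parent template", {
  expect_equal(name_group("Fvirg", "IV", "Av", "p"), "Fvirg-IV-Av-p")
  expect_equal(name_group("Fchil", "VI", "B2", "m"), "Fchil-VI-B2-m")
  expect_error(name_group("Fvirg", "VIII", "Av", "p"), "I\\.\\.VII")
  expect_error(name_group("Fvirg", "IV", "Ax", "p"), "subgenome")
  expect_error(name_group("Fvirg", "IV", "Av", "x"), "parent")
  expect_equal(chromosome_numeral(4), "IV")
})

test_that("grouping recovers planted linkage structure from segregation", {
  # two chromosomes' worth of markers with known gametes
  set.seed(21)
  n_prog <- 40
  gam1 <- matrix(rbinom(n_prog * 1, 1, 0.5), ncol = 1)  # chromosome A
  gam2 <- matrix(rbinom(n_prog * 1, 1, 0.5), ncol = 1)  # chromosome B
  mk <- function(gam, n_mk, noise = 0.02) {
    t(vapply(seq_len(n_mk), function(i) {
      v <- gam[, 1]
      flip <- rbinom(n_prog, 1, noise)
      as.integer(xor(v, flip))
    }, integer(n_prog)))
  }
  seg <- rbind(mk(gam1, 6), mk(gam2, 6))
  chrom <- rep(c("chrA", "chrB"), each = 6)
  pos <- rep(seq(1000, 6000, by = 1000), 2)
  bl <- build_linkage_groups(seg, chrom, pos)
  expect_equal(nrow(bl$groups), 2L)
  expect_true(all(bl$groups$major))
  expect_setequal(bl$groups$primary_chromosome, c("chrA", "chrB"))
  # markers of one chromosome share a group
  expect_equal(length(unique(bl$markers$group[chrom == "chrA"])), 1L)
})
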
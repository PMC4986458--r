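test_that("site classification reproduces the three 2:2 patterns", {
  expect_equal(classify_site("G", "A", "G", "A", sister = "iinumae"),
               "SUPPORTIVE")
  expect_equal(classify_site("A", "A", "G", "G", sister = "iinumae"),
               "INTROGRESSION_LIKE")
  expect_equal(classify_site("T", "A", "A", "T", sister = "iinumae"),
               "OUTGROUP_HOMOPLASY")
  expect_equal(classify_site("A", "A", "A", "A", sister = "iinumae"),
               "UNINFORMATIVE")
  # 3:1 and three-state patterns are uninformative
  expect_equal(classify_site("A", "A", "A", "G", sister = "iinumae"),
               "UNINFORMATIVE")
  expect_equal(classify_site("A", "C", "G", "G", sister = "iinumae"),
               "UNINFORMATIVE")
  expect_equal(classify_site(NA, "A", "G", "G", sister = "iinumae"),
               "UNINFORMATIVE")
  # Av subgenome: sister is vesca
  expect_equal(classify_site("G", "G", "A", "A", sister = "vesca"),
               "SUPPORTIVE")
  expect_equal(classify_site("A", "G", "A", "G", sister = "vesca"),
               "INTROGRESSION_LIKE")
})

test_that("site classification depends only on the base partition", {
  bases <- c("A", "C", "G", "T")
  set.seed(8)
  for (rep in 1:100) {
    x <- sample(bases, 4, replace = TRUE)
    relab <- sample(bases)  # random permutation of the alphabet
    y <- relab[match(x, bases)]
    for (sis in c("vesca", "iinumae")) {
      expect_equal(classify_site(x[1], x[2], x[3], x[4], sister = sis),
                   classify_site(y[1], y[2], y[3], y[4], sister = sis))
    }
  }
})

test_that("region classification follows the support/homoplasy rule", {
  expect_equal(classify_region(rep("SUPPORTIVE", 3)), "SUPPORTIVE")
  expect_equal(classify_region(c("SUPPORTIVE", "INTROGRESSION_LIKE",
                                 "INTROGRESSION_LIKE")),
               "SUPPORT_HOMOPLASY")
  expect_equal(classify_region("INTROGRESSION_LIKE"), "INTROGRESSION_LIKE")
  expect_equal(classify_region(c("INTROGRESSION_LIKE",
                                 "OUTGROUP_HOMOPLASY")),
               "INTROGRESSION_LIKE")
  expect_equal(classify_region("OUTGROUP_HOMOPLASY"), "OUTGROUP")
  expect_true(is.na(classify_region("UNINFORMATIVE")))
})

test_that("cluster detection matches the stated window examples", {
  track <- function(cls) {
    s <- seq_along(cls) * 1000L
    data.frame(class = cls, start = s, end = s + 100L)
  }
  I <- "INTROGRESSION_LIKE"; S <- "SUPPORTIVE"
  expect_equal(nrow(detect_clusters(track(c(I, I)))), 1L)
  expect_equal(detect_clusters(track(c(I, I)))$n_regions, 2L)
  expect_equal(nrow(detect_clusters(track(c(I, S, I)))), 0L)
  r <- detect_clusters(track(c(I, I, I, I, S, I)))
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_regions, 5L)
  # outgroup regions neither support nor break a window
  r2 <- detect_clusters(track(c(I, "OUTGROUP", I)))
  expect_equal(r2$n_regions, 2L)
  # support/homoplasy counts on the supportive side
  expect_equal(nrow(detect_clusters(track(c(I, "SUPPORT_HOMOPLASY", I)))),
               0L)
})

test_that("cluster detection equals brute-force enumeration", {
  classes <- c("INTROGRESSION_LIKE", "SUPPORTIVE", "OUTGROUP",
               "SUPPORT_HOMOPLASY")
  # exhaustive over all tracks of length <= 5
  for (n in 1:5) {
    grid <- expand.grid(rep(list(classes), n), stringsAsFactors = FALSE)
    for (k in seq_len(nrow(grid))) {
      cls <- unlist(grid[k, ], use.names = FALSE)
      s <- seq_len(n) * 1000L
      tr <- data.frame(class = cls, start = s, end = s + 100L)
      expect_identical(detect_clusters(tr), detect_clusters_bruteforce(tr))
    }
  }
  # randomized longer tracks
  set.seed(17)
  for (rep in 1:200) {
    tr <- random_track(sample(6:20, 1))
    expect_identical(detect_clusters(tr)[, c("start", "end", "n_regions")],
                     detect_clusters_bruteforce(tr)[, c("start", "end",
                                                        "n_regions")])
  }
})

test_that("clusters never overlap on the same subgenome and members qualify", {
  set.seed(23)
  for (rep in 1:50) {
    tr <- random_track(sample(5:20, 1))
    cl <- detect_clusters(tr)
    if (nrow(cl) >= 2) {
      o <- order(cl$start)
      expect_true(all(cl$start[o][-1] > cl$end[o][-nrow(cl)]))
    }
    for (i in seq_len(nrow(cl))) {
      inside <- tr$start >= cl$start[i] & tr$end <= cl$end[i]
      ni <- sum(tr$class[inside] == "INTROGRESSION_LIKE")
      expect_gte(ni, 2L)
      # the cluster interval is delimited by introgression-like regions
      first <- which(inside)[1]
      last <- rev(which(inside))[1]
      expect_equal(tr$class[first], "INTROGRESSION_LIKE")
      expect_equal(tr$class[last], "INTROGRESSION_LIKE")
    }
  }
})

test_that("excess homoplasy test uses the exact binomial", {
  r <- excess_homoplasy_test(10, 10)
  expect_equal(r$ratio, 1)
  expect_equal(r$p_binomial, 1)
  r2 <- excess_homoplasy_test(5, 0)
  expect_equal(r2$ratio, Inf)
  expect_equal(r2$p_binomial, 2 * 0.5^5)
  r3 <- excess_homoplasy_test(0, 0)
  expect_true(is.na(r3$p_binomial))
})

test_that("directionality test matches its Fisher construction", {
  d <- directionality_test(48, 0)
  expect_lt(d$p, 0.001)
  expect_equal(d$table["expected", ], c(toward_vesca = 36,
                                        toward_iinumae = 12))
  expect_equal(directionality_test(36, 12)$p, 1)
  expect_equal(directionality_test(3, 1)$p, 1)
})

test_that("cluster geometry sums spans, unions and cross-subgenome overlaps", {
  cl <- data.frame(chrom = c("c1", "c1", "c2"),
                   start = c(100L, 100L, 500L),
                   end = c(400L, 400L, 900L),
                   subgenome = c("B1", "B2", "Bi"))
  g <- cluster_geometry(cl)
  expect_equal(g$n, 3)
  expect_equal(g$span_max, 400L)
  expect_equal(g$union, 300 + 400)      # identical intervals merge
  expect_equal(g$overlap_instances, 1)  # B1 vs B2 on c1
  expect_equal(g$overlap_extent, 300)
  # disjoint clusters: union equals the sum of spans
  cl2 <- data.frame(chrom = "c1", start = c(0L, 1000L), end = c(10L, 1100L),
                    subgenome = c("B1", "B1"))
  expect_equal(cluster_geometry(cl2)$union, 110)
  expect_equal(cluster_geometry(cl2)$overlap_instances, 0)
})

test_that("allele-depth ratios apply the depth and ratio windows", {
  sites <- data.frame(chrom = "c1", pos = c(10L, 20L, 30L, 40L),
                      vesca_depth = c(30, 90, 40, 100),
                      iinumae_depth = c(10, 10, 20, 50))
  clusters <- data.frame(chrom = "c1", start = 25L, end = 45L)
  r <- allele_depth_ratio(sites, clusters)
  # (30,10): combined 40 < 45 excluded; (90,10): ratio 9 > 8 excluded
  expect_equal(r$sites$pos, c(30L, 40L))
  expect_equal(r$sites$ratio, c(2, 2))
  expect_equal(r$sites$in_cluster, c(TRUE, TRUE))
})

test_that("source-informative sites polarize donors against the outgroup", {
  sites <- data.frame(b_base = c("T", "T", "T"),
                      vesca_base = c("T", "C", "T"),
                      av_base = c("C", "T", "T"),
                      outgroup_base = c("C", "C", "C"))
  r <- source_informative_sites(sites)
  expect_equal(r$vesca_only, 1)
  expect_equal(r$av_only, 1)
})
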
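test_that("pairwise distances match hand-worked examples", {
  gt <- toy_table()
  dps <- pairwise_genetic_distance(gt, "dps")
  eu <- pairwise_genetic_distance(gt, "euclidean")
  # a vs c: L1 AA vs BB (no sharing), L2 AB vs AA (one copy of two)
  expect_equal(dps$values["a", "c"], 0.75)
  # dosage (2,0) vs (0,2) at L1 -> squared 8; (1,1) vs (2,0) at L2 -> 2
  expect_equal(eu$values["a", "c"], sqrt(10))
  expect_true(isSymmetric(dps$values))
  expect_equal(unname(diag(dps$values)), rep(0, 3))
  # single diallelic locus AA vs BB: euclidean 2*sqrt(2), dps 1
  g1 <- genotype_table(c("x", "y"), 0:1, 0:1,
                       list(L = rbind(c("A", "A"), c("B", "B"))))
  expect_equal(pairwise_genetic_distance(g1, "euclidean")$values["x", "y"],
               2 * sqrt(2))
  expect_equal(pairwise_genetic_distance(g1, "dps")$values["x", "y"], 1)
  # AB vs AC shares one allele copy of two
  g2 <- genotype_table(c("x", "y"), 0:1, 0:1,
                       list(L = rbind(c("A", "B"), c("A", "C"))))
  expect_equal(pairwise_genetic_distance(g2, "dps")$values["x", "y"], 0.5)
  # 0/0.5/1 dosage scaling changes euclidean by a constant factor
  eu2 <- pairwise_genetic_distance(gt, "euclidean", dosage_scale = 0.5)
  expect_equal(eu2$values, eu$values / 2)
})

test_that("identical genotypes give zero distance and QG relatedness 1", {
  base <- random_hwe_table(10, 4L, 5L, seed = 2)
  # append a clone of the first individual
  genos <- lapply(seq_len(n_loci(base)), function(l)
    rbind(cbind(base$a1[, l], base$a2[, l]),
          c(base$a1[1L, l], base$a2[1L, l])))
  names(genos) <- base$loci
  gt <- genotype_table(c(base$id, "clone"), c(base$x, base$x[1L]),
                       c(base$y, base$y[1L]), genos)
  dps <- pairwise_genetic_distance(gt, "dps")
  eu <- pairwise_genetic_distance(gt, "euclidean")
  qg <- pairwise_genetic_distance(gt, "qg")
  expect_equal(dps$values["i001", "clone"], 0)
  expect_equal(eu$values["i001", "clone"], 0)
  expect_equal(unname(diag(qg$relatedness)), rep(1, 11))
})

test_that("QG relatedness averages near zero under random mating", {
  gt <- random_hwe_table(150, 6L, 5L, seed = 11)
  qg <- pairwise_genetic_distance(gt, "qg")
  r <- qg$relatedness[lower.tri(qg$relatedness)]
  expect_lt(abs(mean(r)), 0.02)
})

test_that("euclidean distance satisfies the triangle inequality", {
  gt <- random_hwe_table(12, 4L, 4L, seed = 3)
  d <- pairwise_genetic_distance(gt, "euclidean")$values
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12) {
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-9)
  }
})

test_that("pairs with missing loci drop them; zero-shared pairs are NA", {
  genos <- list(L1 = rbind(c("A", "B"), c("A", "A"), c(NA, NA)),
                L2 = rbind(c(NA, NA), c("C", "C"), c("C", "D")))
  gt <- genotype_table(c("a", "b", "c"), 1:3, 1:3, genos)
  expect_warning(dps <- pairwise_genetic_distance(gt, "dps"), "no typed locus")
  expect_true(is.na(dps$values["a", "c"])) # disjoint typed loci
  expect_equal(dps$n_loci_used["a", "b"], 1L)
  expect_equal(dps$values["a", "b"], 0.5) # only L1 compared
})

test_that("Mantel test recovers perfect, inverted and null relations", {
  set.seed(4)
  xy <- cbind(runif(30, 0, 1e4), runif(30, 0, 1e4))
  geo <- as.matrix(dist(xy))
  m <- mantel_test(geo * 2.5, geo, n_perm = 199, seed = 1)
  expect_equal(m$r, 1)
  expect_lte(m$p_value, 1 / 200 + 1e-12)
  m2 <- mantel_test(-geo, geo, n_perm = 99, seed = 1)
  expect_equal(m2$r, -1)
  expect_error(mantel_test(matrix(1, 5, 5), geo[1:5, 1:5]), "constant")
  # independent matrices: small r, typically non-significant
  reps <- vapply(1:20, function(s) {
    set.seed(s)
    a <- as.matrix(dist(runif(40)))
    b <- as.matrix(dist(runif(40)))
    mt <- mantel_test(a, b, n_perm = 99, seed = s)
    c(mt$r, mt$p_value)
  }, numeric(2))
  expect_gte(mean(abs(reps[1, ]) < 0.1), 0.9)
  expect_gte(mean(reps[2, ] > 0.05), 0.75)
})

test_that("Mantel r agrees with vegan and the bootstrap CI covers r", {
  set.seed(9)
  xy <- cbind(runif(25, 0, 1e4), runif(25, 0, 1e4))
  geo <- as.matrix(dist(xy))
  gd <- geo + as.matrix(dist(rnorm(25, sd = 2000)))
  ours <- mantel_test(gd, geo, n_perm = 199, n_boot = 100, seed = 1)
  ref <- vegan::mantel(as.dist(gd), as.dist(geo), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_true(ours$ci95[1] <= ours$r && ours$r <= ours$ci95[2])
})

test_that("correlogram is invariant to joint relabeling and finds crossings", {
  gt <- random_hwe_table(40, 5L, 4L, seed = 21)
  gd <- pairwise_genetic_distance(gt, "dps")
  geo <- geographic_distance_matrix(gt)
  cg <- mantel_correlogram(gd, geo, class_width = 2e4, n_perm = 49, seed = 2)
  perm <- sample(40)
  gd2 <- gd; gd2$values <- gd$values[perm, perm]; gd2$ids <- gd$ids[perm]
  geo2 <- geo; geo2$values <- geo$values[perm, perm]
  cg2 <- mantel_correlogram(gd2, geo2, class_width = 2e4, n_perm = 49,
                            seed = 2)
  expect_equal(cg$r, cg2$r)
  # spatially unstructured genotypes: no excess of significant positive
  # classes at the 5% level
  sig_pos <- sum(cg$r > 0 & cg$p_value < 0.05)
  expect_lte(sig_pos, 1L)
  # a distance matrix that increases then saturates crosses zero
  set.seed(1)
  xy <- cbind(runif(60, 0, 6e4), runif(60, 0, 6e4))
  geo3 <- as.matrix(dist(xy))
  gd3 <- pmin(geo3, 2e4) + matrix(rnorm(3600, sd = 800), 60)
  gd3 <- (gd3 + t(gd3)) / 2; diag(gd3) <- 0
  cg3 <- mantel_correlogram(gd3, geo3, class_width = 5e3, n_perm = 19,
                            seed = 1)
  expect_false(is.na(zero_crossing(cg3)))
})

test_that("neighborhood allelic richness follows the g rule and allele pools", {
  # all samples within radius: one shared neighborhood, constant richness
  gt <- random_hwe_table(12, 3L, 4L, seed = 6)
  gt$x <- runif(12, 0, 100); gt$y <- runif(12, 0, 100)
  nr <- neighborhood_allelic_richness(gt, radius = 1e4, min_n = 5)
  expect_equal(attr(nr, "g"), 24L)
  expect_equal(length(unique(round(nr$richness, 10))), 1L)
  # two demes with different allele pools: richer deme scores higher
  set.seed(8)
  n <- 16
  gA <- cbind(sample(c("A", "B", "C", "D", "E", "F"), n, TRUE),
              sample(c("A", "B", "C", "D", "E", "F"), n, TRUE))
  gB <- cbind(sample(c("A", "B"), n, TRUE), sample(c("A", "B"), n, TRUE))
  gt2 <- genotype_table(
    sprintf("s%02d", 1:(2 * n)),
    x = c(runif(n, 0, 50), runif(n, 1e5, 1e5 + 50)),
    y = rep(0, 2 * n),
    genotypes = list(L = rbind(gA, gB)))
  nr2 <- neighborhood_allelic_richness(gt2, radius = 1000, min_n = 10)
  expect_gt(mean(nr2$richness[1:n]), mean(nr2$richness[(n + 1):(2 * n)]))
  expect_error(neighborhood_allelic_richness(gt2, radius = 1000, min_n = 40),
               "no neighborhood")
})

test_that("pairwise long CSV export carries all metrics", {
  gt <- toy_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairwise_long(path, geographic_distance_matrix(gt),
                      dps = pairwise_genetic_distance(gt, "dps"),
                      euclidean = pairwise_genetic_distance(gt, "euclidean"))
  df <- read.csv(path)
  expect_equal(nrow(df), 3L)
  expect_named(df, c("id1", "id2", "geo_m", "dps", "euclidean", "n_loci"))
})
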
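test_that("ANOSIM and PERMANOVA statistics agree with vegan on random data", {
  set.seed(42)
  x <- matrix(rpois(30 * 12, 20) + 1, 12, 30)
  rownames(x) <- paste0("s", 1:12)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- dist(x)
  dm <- dist_matrix(as.matrix(d))
  expect_equal(anosim(dm, g, n_perm = 99, seed = 1)$statistic,
               vegan::anosim(d, g, permutations = 99)$statistic,
               tolerance = 1e-10)
  pe <- permanova(dm, g, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(pe$statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(unname(pe$effect_partition["group"]), ad$R2[1],
               tolerance = 1e-10)
  set.seed(5)
  y <- matrix(rnorm(24), 12, 2)
  rownames(y) <- rownames(x)
  d2 <- dist_matrix(as.matrix(dist(y)))
  expect_equal(mantel(dm, d2, n_perm = 99, seed = 1)$statistic,
               vegan::mantel(d, dist(y), method = "spearman",
                             permutations = 99)$statistic,
               tolerance = 1e-10)
})

test_that("complete group separation gives ANOSIM R = 1", {
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- dist_matrix(as.matrix(dist(x)))
  g <- rep(c("lo", "hi"), each = 3)
  expect_equal(anosim(d, g, n_perm = 99, seed = 1)$statistic, 1)
})

test_that("PERMANOVA sums of squares match the brute-force double loop", {
  for (seed in 1:5) {
    d <- random_dist(6, seed = seed)
    g <- c("a", "a", "a", "b", "b", "b")
    mine <- permanova(d, g, n_perm = 49, seed = 1)
    ref <- brute_permanova(d$values, g)
    expect_equal(mine$statistic, ref$F, tolerance = 1e-10)
    expect_equal(mine$ss_total, ref$ss_t, tolerance = 1e-10)
    expect_equal(mine$ss_within, ref$ss_w, tolerance = 1e-10)
    expect_equal(unname(mine$effect_partition["group"]), ref$R2,
                 tolerance = 1e-10)
  }
})

test_that("degenerate within-group spread is flagged as maximal F", {
  x <- rep(c(0, 1), each = 3)
  d <- dist_matrix(as.matrix(dist(x)))
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(d, g, n_perm = 49, seed = 1)
  expect_true(is.infinite(res$statistic))
  expect_identical(res$flag, "maximal_F")
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("Mantel is 1 for self and monotone transforms, flagged when constant", {
  d <- random_dist(8, seed = 3)
  expect_equal(mantel(d, d, n_perm = 99, seed = 1)$statistic, 1)
  d2 <- dist_matrix(d$values^2)  # monotone transform: same ranks
  expect_equal(mantel(d, d2, n_perm = 99, seed = 1)$statistic, 1)
  const <- dist_matrix(matrix(1, 8, 8) - diag(8),
                       metric = "constant")
  const$sample_ids <- d$sample_ids
  rownames(const$values) <- colnames(const$values) <- d$sample_ids
  res <- mantel(d, const, n_perm = 99, seed = 1)
  expect_identical(res$flag, "degenerate")
  expect_true(is.na(res$statistic))
})

test_that("Mantel is invariant to relabeling applied to both matrices", {
  d1 <- random_dist(9, seed = 5)
  d2 <- random_dist(9, p = 2, seed = 6)
  r0 <- mantel(d1, d2, n_perm = 49, seed = 1)$statistic
  perm <- c(3, 1, 2, 9, 8, 4, 5, 7, 6)
  p1 <- dist_matrix(d1$values[perm, perm])
  p2 <- dist_matrix(d2$values[perm, perm])
  p2$sample_ids <- p1$sample_ids
  expect_equal(mantel(p1, p2, n_perm = 49, seed = 1)$statistic, r0,
               tolerance = 1e-12)
})

test_that("permutation p-values are never zero and reproducible under a seed", {
  d <- random_dist(10, seed = 9)
  g <- rep(c("a", "b"), each = 5)
  r1 <- anosim(d, g, n_perm = 199, seed = 7)
  r2 <- anosim(d, g, n_perm = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_equal(r1$n_permutations, 199)
})

test_that("BH adjustment matches the worked example and edge cases", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
})

test_that("haversine distances use the mean Earth radius and validate input", {
  h <- haversine_matrix(data.frame(latitude_deg = c(0, 0),
                                   longitude_deg = c(0, 180)))
  expect_equal(h$values[1, 2], pi * 6371.0088, tolerance = 1e-6)
  expect_equal(h$values[1, 1], 0)
  set.seed(2)
  co <- data.frame(latitude_deg = runif(5, -60, 60),
                   longitude_deg = runif(5, -150, 150))
  hm <- haversine_matrix(co)$values
  expect_equal(hm, t(hm))
  expect_error(haversine_matrix(data.frame(latitude_deg = 91,
                                           longitude_deg = 0)), "latitude")
  expect_error(haversine_matrix(data.frame(latitude_deg = 0,
                                           longitude_deg = -190)), "longitude")
})

test_that("scale_center standardizes columns and drops constants", {
  expect_equal(as.numeric(scale_center(matrix(c(1, 2, 3), 3, 1))),
               c(-1, 0, 1))
  z <- matrix(rnorm(30), 10, 3)
  z <- scale(z)
  expect_equal(scale_center(z), matrix(as.numeric(z), 10, 3,
                                       dimnames = dimnames(scale_center(z))),
               tolerance = 1e-12, ignore_attr = TRUE)
  m <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_warning(out <- scale_center(m), "constant")
  expect_equal(colnames(out), "b")
})

test_that("NMDS recovers exact embeddings and flags impossible ones", {
  set.seed(4)
  pts <- matrix(rnorm(16), 8, 2)
  rownames(pts) <- paste0("s", 1:8)
  d <- dist_matrix(as.matrix(dist(pts)))
  fit <- nmds(d, k = 2, n_restarts = 10, seed = 1)
  expect_lt(fit$stress, 1e-4)
  # a generic 6-dimensional configuration cannot embed in the plane with its
  # dissimilarity ranks preserved, so stress stays positive
  set.seed(8)
  hi <- matrix(rnorm(60), 10, 6)
  rownames(hi) <- paste0("s", 1:10)
  fit4 <- nmds(dist_matrix(as.matrix(dist(hi))), k = 2, n_restarts = 10,
               seed = 1)
  expect_gt(fit4$stress, 1e-3)
  # a duplicated sample (d = 0) ends up coincident
  pts2 <- rbind(pts, s9 = pts[1, ])
  dd <- dist_matrix(as.matrix(dist(pts2)))
  fit9 <- nmds(dd, k = 2, n_restarts = 10, seed = 1)
  dup <- sqrt(sum((fit9$coordinates["s1", ] - fit9$coordinates["s9", ])^2))
  expect_lt(dup, 0.05 * max(dist(fit9$coordinates)))
  expect_error(nmds(dist_matrix(matrix(0, 2, 2)), k = 2), "at least")
})

test_that("group preconditions are enforced", {
  d <- random_dist(5, seed = 1)
  expect_error(anosim(d, c("a", "a", "a", "a", "b"), n_perm = 9),
               "fewer than 2")
  expect_error(permanova(d, rep("a", 5), n_perm = 9), "at least 2 groups")
})
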
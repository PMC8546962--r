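test_that("relative abundance closes each sample to 1", {
  m <- matrix(c(2, 2, 1, 3, 9, 27), 2, 3, byrow = FALSE)
  dimnames(m) <- list(c("f1", "f2"), c("s1", "s2", "s3"))
  tab <- count_table(matrix(c(1, 3, 9, 27), 4, 1,
                            dimnames = list(paste0("f", 1:4), "s1")), "16S")
  expect_equal(as.numeric(relative_abundance(tab)),
               c(0.025, 0.075, 0.225, 0.675))
  expect_equal(as.numeric(relative_abundance(matrix(c(2, 2), 2, 1))),
               c(0.5, 0.5))
  expect_equal(as.numeric(relative_abundance(matrix(5, 1, 3))), rep(1, 3))
  z <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(NULL, c("ok", "empty")))
  expect_error(relative_abundance(z), "empty")
})

test_that("CLR matches the closed form and its invariances", {
  x <- matrix(c(1, 3, 9), 3, 1, dimnames = list(paste0("f", 1:3), "s1"))
  expect_equal(as.numeric(clr_transform(x)), c(-log(3), 0, log(3)),
               tolerance = 1e-12)
  expect_equal(as.numeric(clr_transform(matrix(1, 4, 1))), rep(0, 4))
  expect_equal(clr_transform(x * 2), clr_transform(x), tolerance = 1e-12)
  expect_error(clr_transform(matrix(-1, 1, 1)), "non-negative")
})

test_that("CLR zero-sum and scale invariance hold on fuzzed tables with zeros", {
  set.seed(101)
  for (i in 1:50) {
    n_f <- sample(3:12, 1); n_s <- sample(2:8, 1)
    m <- matrix(rpois(n_f * n_s, 3), n_f, n_s)
    m[sample(length(m), length(m) %/% 4)] <- 0
    m[1, ] <- m[1, ] + 1  # keep totals positive
    for (policy in c("multiplicative", "add_one")) {
      clr <- clr_transform(m, pseudocount = policy)
      expect_lt(max(abs(colSums(clr))), 1e-9)
      scaled <- sweep(m, 2, sample(1:5, n_s, replace = TRUE), "*")
      expect_equal(clr_transform(scaled, pseudocount = "multiplicative"),
                   clr_transform(m, pseudocount = "multiplicative"),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("Aitchison distance is Euclidean on CLR vectors", {
  clr <- cbind(s1 = c(0, 0), s2 = c(1, -1))
  d <- aitchison_distance(clr)
  expect_equal(d$values["s1", "s2"], sqrt(2))
  expect_equal(diag(d$values), c(s1 = 0, s2 = 0))

  set.seed(7)
  m <- matrix(rpois(25, 8) + 1, 5, 5,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:5)))
  tab <- count_table(m, "ITS")
  d2 <- aitchison_distance(tab)
  clr2 <- clr_transform(tab)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(d2$values[i, j], sqrt(sum((clr2[, i] - clr2[, j])^2)),
                 tolerance = 1e-12)
  # permuting feature order leaves the distances unchanged
  perm <- sample(5)
  d3 <- aitchison_distance(count_table(m[perm, ], "ITS"))
  expect_equal(d3$values, d2$values, tolerance = 1e-12)
  # scale invariance through the whole chain
  d4 <- aitchison_distance(count_table(sweep(m, 2, c(1, 2, 3, 4, 5), "*"), "ITS"))
  expect_equal(d4$values, d2$values, tolerance = 1e-9)
})

test_that("core microbiome applies the prevalence/abundance rule and is monotone", {
  # f1: 5% in all 10 samples; f2: 5% in 8 of 10; f3: below floor everywhere
  m <- rbind(f1 = rep(5, 10),
             f2 = c(rep(5, 8), 0, 0),
             f3 = c(rep(0.4, 10)),
             f4 = rep(89.6, 10) + c(rep(0, 8), 5, 5))
  m <- round(m * 10)
  tab <- count_table(m, "ITS")
  expect_setequal(core_microbiome(tab, 0.90, 0.01), c("f1", "f4"))
  expect_true("f2" %in% core_microbiome(tab, 0.80, 0.01))
  expect_equal(core_microbiome(count_table(matrix(0L, 0, 0), "ITS")),
               character(0))
  # monotonicity: raising either threshold never adds features
  set.seed(11)
  mm <- matrix(rpois(200, 4), 20, 10,
               dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  mm[1, ] <- mm[1, ] + 5
  tt <- count_table(mm, "16S")
  for (pr in c(0.5, 0.7, 0.9)) {
    expect_true(all(core_microbiome(tt, pr, 0.05) %in%
                      core_microbiome(tt, pr, 0.01)))
  }
  for (ab in c(0.01, 0.05)) {
    expect_true(all(core_microbiome(tt, 0.9, ab) %in%
                      core_microbiome(tt, 0.5, ab)))
  }
})

test_that("alpha diversity matches closed forms", {
  uni <- count_table(matrix(25L, 4, 1, dimnames = list(paste0("f", 1:4), "s1")),
                     "16S")
  expect_equal(unname(alpha_diversity(uni, "shannon")), log(4),
               tolerance = 1e-12)
  tri <- count_table(matrix(c(1L, 1L, 2L), 3, 1,
                            dimnames = list(paste0("f", 1:3), "s1")), "16S")
  expect_equal(unname(alpha_diversity(tri, "chao1")), 3.5)
  nos <- count_table(matrix(c(5L, 7L, 9L), 3, 1,
                            dimnames = list(paste0("f", 1:3), "s1")), "16S")
  expect_equal(unname(alpha_diversity(nos, "chao1")), 3)  # F1 = 0
  zz <- count_table(matrix(c(1L, 0L), 1, 2,
                           dimnames = list("f1", c("a", "b"))), "16S")
  expect_error(alpha_diversity(zz, "shannon"), "b")
})
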
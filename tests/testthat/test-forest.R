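gauss2 <- function(n_per = 30, sep = 3, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  colnames(x) <- paste0("f", seq_len(p))
  y <- factor(rep(c("a", "b"), each = n_per))
  x[, 1] <- x[, 1] + ifelse(y == "a", sep, 0)
  list(x = x, y = y)
}

test_that("stratified 70:30 splits respect class arithmetic", {
  y <- factor(rep(letters[1:3], each = 10))
  part <- partition(y, "split70", seed = 3)
  expect_equal(as.vector(table(y[part$train])), rep(7L, 3))
  expect_equal(as.vector(table(y[part$test])), rep(3L, 3))
  expect_length(intersect(part$train, part$test), 0)
  expect_error(partition(factor(c("a", "a", "b")), "split70", seed = 1),
               "cannot stratify")
})

test_that("leave-one-vintage-out holds out exactly the target vintage", {
  y <- factor(rep(c("s1", "s2"), 6))
  vin <- rep(c("2017", "2019"), each = 6)
  part <- partition(y, "lovo", vintage = vin, holdout_vintage = "2019")
  expect_true(all(vin[part$test] == "2019"))
  expect_true(all(vin[part$train] == "2017"))
  # a class confined to the held-out vintage cannot be trained on
  y2 <- factor(c(rep("s1", 6), rep("s2", 6)))
  expect_error(partition(y2, "lovo", vintage = vin,
                         holdout_vintage = "2019"), "absent from the training")
})

test_that("accuracy and kappa match closed-form confusion examples", {
  diag3 <- diag(c(4, 5, 6))
  ev <- kappa_from_confusion(diag3)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$kappa, 1)
  ev2 <- kappa_from_confusion(matrix(c(3, 2, 2, 3), 2, 2))
  expect_equal(ev2$accuracy, 0.6)
  expect_equal(ev2$kappa, 0.2)
  # one-class predictions on a balanced test set: agreement equals chance
  ev3 <- kappa_from_confusion(matrix(c(5, 5, 0, 0), 2, 2))
  expect_equal(ev3$kappa, 0)
  expect_error(evaluate(factor("a"), y_test = factor(character(0))), "empty")
})

test_that("forests separate well-separated classes and are seed-deterministic", {
  d <- gauss2(sep = 5)
  part <- partition(d$y, "split70", seed = 2)
  fit <- fit_forest(d$x[part$train, ], d$y[part$train], num_trees = 300,
                    seed = 5)
  ev <- evaluate(fit, d$x[part$test, ], d$y[part$test])
  expect_gt(ev$accuracy, 0.95)
  fit2 <- fit_forest(d$x[part$train, ], d$y[part$train], num_trees = 300,
                     seed = 5)
  expect_identical(predict(fit, d$x[part$test, ]),
                   predict(fit2, d$x[part$test, ]))
  expect_error(fit_forest(d$x[1:10, ], factor(rep("a", 10))), "single class")
})

test_that("shuffled labels give chance-level accuracy", {
  d <- gauss2(n_per = 20)
  accs <- sapply(1:10, function(s) {
    set.seed(s)
    ys <- sample(d$y)
    part <- partition(ys, "split70", seed = s)
    fit <- fit_forest(d$x[part$train, ], ys[part$train], num_trees = 150,
                      seed = s)
    evaluate(fit, d$x[part$test, ], ys[part$test])$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("tuning searches the grid and still fits deterministically", {
  d <- gauss2(n_per = 15)
  fit <- fit_forest(d$x, d$y, num_trees = 200, tune = TRUE, seed = 4)
  expect_true(fit$hyperparameters$mtry %in%
                unique(pmax(1, floor(c(sqrt(6), 6 / 5, 3)))))
  expect_true(fit$hyperparameters$sample_fraction %in% c(0.632, 0.8, 1.0))
  expect_true(fit$hyperparameters$min_node_size %in% c(1, 5, 10))
})

test_that("casewise importance concentrates on the predictive feature", {
  d <- gauss2(n_per = 30, sep = 4)
  fit <- fit_forest(d$x, d$y, num_trees = 300, seed = 7)
  cw <- casewise_importance(fit)
  cm <- colMeans(cw, na.rm = TRUE)
  expect_gt(cm["f1"], 5 * max(abs(cm[-1])))
  # a feature unused by every tree has (near) zero importance everywhere
  expect_lt(max(abs(cm[-1])), 0.05)
  expect_equal(dim(cw), c(60, 6))
})

test_that("casewise column means reconcile with the per-tree OOB oracle", {
  d <- gauss2(n_per = 25, sep = 2.5)
  fit <- fit_forest(d$x, d$y, num_trees = 200, seed = 9)
  cw <- casewise_importance(fit)
  oracle <- permutation_importance(fit, d$x, d$y, oob = TRUE, seed = 11)
  expect_gt(cor(colMeans(cw, na.rm = TRUE), oracle), 0.95)
  # and both agree with ranger's own global permutation importance
  expect_gt(cor(oracle, fit$rf$variable.importance), 0.95)
})

test_that("vita selects perfect predictors and rejects degenerate features", {
  set.seed(12)
  n <- 40
  x <- matrix(rnorm(n * 20), n, 20)
  colnames(x) <- paste0("f", 1:20)
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[, 1] <- as.integer(y) + rnorm(n, 0, 0.01)  # copy of the label
  x[, 2] <- 1                                  # zero variance
  vs <- vita_select(x, y, num_trees = 150, seed = 3)
  expect_true("f1" %in% vs$selected)
  expect_false("f2" %in% vs$selected)
  expect_equal(unname(vs$importance["f2"]), 0)
})

test_that("vita stays near its nominal false-selection rate on pure noise", {
  fracs <- sapply(1:10, function(s) {
    set.seed(1000 + s)
    n <- 40
    x <- matrix(rnorm(n * 500), n, 500)
    colnames(x) <- paste0("f", 1:500)
    y <- factor(rep(c("a", "b"), each = n / 2))
    vs <- vita_select(x, y, num_trees = 100, seed = s)
    length(vs$selected) / 500
  })
  expect_lte(mean(fracs), 2 * 0.05)
})

test_that("fold reduction for small classes is reported", {
  set.seed(5)
  x <- matrix(rnorm(8 * 10), 8, 10)
  colnames(x) <- paste0("f", 1:10)
  y <- factor(rep(c("a", "b"), each = 4))
  expect_warning(vita_select(x, y, n_folds = 5, num_trees = 50, seed = 1),
                 "reducing folds")
})
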
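#' Train/test partitioning schemes
#'
#' `"split70"` draws a stratified random 70:30 split so every class is
#' represented proportionally in both sets; `"lovo"` (leave-one-vintage-out)
#' trains on all samples from the other vintages and tests on the held-out
#' vintage, the cross-vintage validation used for vintage-robust signatures.
#'
#' @param labels class label per sample (site or region).
#' @param scheme `"split70"` or `"lovo"`.
#' @param vintage vintage per sample (required for `"lovo"`).
#' @param holdout_vintage the vintage to hold out under `"lovo"`.
#' @param train_frac training fraction for `"split70"` (default 0.7).
#' @param seed integer seed for the random split.
#' @return list with integer index vectors `train` and `test`.
#' @export
partition <- function(labels, scheme = c("split70", "lovo"), vintage = NULL,
                      holdout_vintage = NULL, train_frac = 0.7, seed = NULL) {
  scheme <- match.arg(scheme)
  labels <- as.factor(labels)
  n <- length(labels)
  if (scheme == "split70") {
    if (!is.null(seed)) set.seed(seed)
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2)
        .stopf("class '%s' has %d sample(s): cannot stratify a 70:30 split",
               cl, length(idx))
      k <- max(1L, floor(train_frac * length(idx) + 0.5))
      if (k >= length(idx)) k <- length(idx) - 1L
      train <- c(train, sample(idx, k))
    }
    train <- sort(train)
    test <- setdiff(seq_len(n), train)
  } else {
    if (is.null(vintage) || is.null(holdout_vintage))
      .stopf("leave-one-vintage-out needs vintage labels and a holdout vintage")
    test <- which(vintage == holdout_vintage)
    train <- which(vintage != holdout_vintage)
    if (length(test) == 0) .stopf("no samples from vintage '%s'", holdout_vintage)
  }
  missing_cl <- setdiff(levels(droplevels(labels)),
                        levels(droplevels(labels[train])))
  if (length(missing_cl) > 0)
    .stopf("class '%s' absent from the training set", missing_cl[1])
  list(train = train, test = test)
}

#' Fit a seeded random-forest classifier
#'
#' Bagged randomized-tree classifier via `ranger` with permutation importance
#' and casewise (local) importance retained, deterministic given `seed`.
#' With `tune = TRUE` the hyperparameters `mtry`, `sample.fraction`, and
#' `min.node.size` are chosen by out-of-bag error over the grid
#' mtry in \{sqrt(p), p/5, p/2\}, sample fraction in \{0.632, 0.8, 1.0\},
#' min node size in \{1, 5, 10\} (ties broken toward the first, i.e. most
#' conventional, combination), then the forest is refit at full size.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y class labels.
#' @param num_trees number of trees (default 10000; reduce for quick runs).
#' @param tune tune hyperparameters by OOB error (default FALSE).
#' @param mtry,sample_fraction,min_node_size fixed hyperparameters used when
#'   `tune = FALSE` (defaults: ranger's sqrt(p), 1.0, 1).
#' @param seed integer seed.
#' @return an object of class `forest_model` wrapping the ranger fit.
#' @export
fit_forest <- function(x, y, num_trees = 10000, tune = FALSE,
                       mtry = NULL, sample_fraction = 1, min_node_size = 1,
                       seed = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) .stopf("training data contain a single class")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  df <- as.data.frame(x)
  names(df) <- colnames(x) <- .safe_names(colnames(x), p)
  hp <- list(mtry = if (is.null(mtry)) max(1L, floor(sqrt(p))) else mtry,
             sample_fraction = sample_fraction,
             min_node_size = min_node_size)
  if (tune) {
    grid <- expand.grid(
      mtry = unique(pmax(1L, floor(c(sqrt(p), p / 5, p / 2)))),
      sample_fraction = c(0.632, 0.8, 1.0),
      min_node_size = c(1L, 5L, 10L)
    )
    oob <- vapply(seq_len(nrow(grid)), function(i) {
      fit <- ranger::ranger(
        x = df, y = y, num.trees = max(200L, ceiling(num_trees / 20)),
        mtry = grid$mtry[i], sample.fraction = grid$sample_fraction[i],
        min.node.size = grid$min_node_size[i], seed = seed,
        num.threads = 1, verbose = FALSE)
      fit$prediction.error
    }, 0)
    best <- which.min(oob)  # which.min takes the first minimum: fixed tie-break
    hp <- as.list(grid[best, ])
  }
  rf <- ranger::ranger(
    x = df, y = y, num.trees = num_trees, mtry = hp$mtry,
    sample.fraction = hp$sample_fraction, min.node.size = hp$min_node_size,
    importance = "permutation", local.importance = TRUE, keep.inbag = TRUE,
    seed = seed, num.threads = 1, verbose = FALSE)
  structure(list(rf = rf, hyperparameters = hp, seed = seed,
                 feature_names = colnames(x), classes = levels(y),
                 n_train = nrow(x)),
            class = "forest_model")
}

# ranger needs syntactically safe column names; keep a reversible mapping.
.safe_names <- function(nm, p) {
  if (is.null(nm)) nm <- sprintf("feat%05d", seq_len(p))
  nm
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model: %d trees, %d features, %d classes, OOB error %.3f\n",
              x$rf$num.trees, length(x$feature_names), length(x$classes),
              x$rf$prediction.error))
  invisible(x)
}

#' Predict classes with a fitted forest
#' @param object a `forest_model`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.forest_model <- function(object, newdata, ...) {
  df <- as.data.frame(as.matrix(newdata))
  names(df) <- object$feature_names
  predict(object$rf, data = df, num.threads = 1, verbose = FALSE)$predictions
}

#' Evaluate a classifier on a test set
#'
#' Confusion matrix (rows = truth, columns = prediction), accuracy
#' (trace over total), and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the product
#' of the marginals.
#'
#' @param model a `forest_model` (or a factor of predictions).
#' @param x_test test feature matrix (ignored when predictions are given).
#' @param y_test true labels.
#' @return list with `confusion`, `accuracy`, `kappa`.
#' @export
evaluate <- function(model, x_test = NULL, y_test) {
  if (length(y_test) == 0) .stopf("empty test set")
  pred <- if (inherits(model, "forest_model")) {
    predict(model, x_test)
  } else {
    model
  }
  lev <- union(levels(as.factor(y_test)), levels(as.factor(pred)))
  truth <- factor(y_test, levels = lev)
  pred <- factor(pred, levels = lev)
  cm <- table(truth = truth, predicted = pred)
  kappa_from_confusion(cm)
}

#' Accuracy and Cohen's kappa from a confusion matrix
#' @param cm square confusion matrix, rows = truth.
#' @return list with `confusion`, `accuracy`, `kappa`.
#' @export
kappa_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  list(confusion = cm, accuracy = p_o, kappa = kappa)
}

#' Casewise (local) permutation importance
#'
#' Per-training-sample contribution to each feature's permutation
#' importance: entry (i, j) is the mean, over the trees for which sample i is
#' out-of-bag, of the drop in correct-vote indicator after permuting feature
#' j among that tree's out-of-bag samples.  Computed from the fitted
#' ensemble's stored local importances, rescaled by each sample's
#' out-of-bag tree count (the raw values are averaged over all trees).
#' The per-feature mean of this matrix reconciles with the forest's global
#' permutation importance up to Monte-Carlo error.
#'
#' @param model a `forest_model` fitted by [fit_forest()].
#' @return samples x features matrix; rows for samples that were never
#'   out-of-bag are `NA` and flagged via attribute `"never_oob"`.
#' @export
casewise_importance <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  rf <- model$rf
  if (is.null(rf$variable.importance.local))
    .stopf("model was fitted without local importance")
  local <- rf$variable.importance.local
  inbag <- do.call(cbind, rf$inbag.counts)
  oob_n <- rowSums(inbag == 0)
  never <- which(oob_n == 0)
  scale <- ifelse(oob_n > 0, rf$num.trees / oob_n, NA_real_)
  out <- local * scale
  if (length(never) > 0) {
    out[never, ] <- NA_real_
    .warnf("%d training sample(s) never out-of-bag", length(never))
  }
  attr(out, "never_oob") <- never
  out
}

#' Monte-Carlo per-tree permutation importance
#'
#' Estimator of permutation variable importance computed tree by tree: for
#' every tree the accuracy on the evaluation samples is compared before and
#' after permuting one feature, and the drops are averaged over trees (and
#' over `n_rep` permutations).  Working per tree rather than on the
#' aggregated forest prediction avoids the masking that correlated features
#' cause in whole-model permutation importance.  Two evaluation modes:
#' \describe{
#'   \item{hold-out (`oob = FALSE`)}{every tree is evaluated on all rows of
#'     `(x, y)`, which should be data not used for training — the engine of
#'     [vita_select()];}
#'   \item{out-of-bag (`oob = TRUE`)}{`(x, y)` must be the training data in
#'     training order, and each tree is evaluated only on its out-of-bag
#'     samples — an independent recomputation of the forest's global
#'     permutation importance, used to cross-check the casewise matrix.}
#' }
#' Predictions for all permuted copies are batched through chunked
#' `predict.all` calls.
#'
#' @param model a `forest_model`.
#' @param x feature matrix (samples x features).
#' @param y true labels.
#' @param oob evaluate per tree on its out-of-bag samples (see Details).
#' @param n_rep permutations per feature (default 1).
#' @param seed integer seed.
#' @param chunk maximum features per batched prediction call.
#' @return named numeric vector of importance (mean per-tree accuracy drops).
#' @export
permutation_importance <- function(model, x, y, oob = FALSE, n_rep = 1,
                                   seed = 1, chunk = 50) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  rf <- model$rf
  lev <- rf$forest$levels
  y_code <- match(as.character(y), lev)
  df <- as.data.frame(x)
  names(df) <- model$feature_names
  base_pred <- predict(rf, df, predict.all = TRUE, num.threads = 1,
                       verbose = FALSE)$predictions
  if (oob) {
    inbag <- do.call(cbind, rf$inbag.counts)
    if (nrow(inbag) != n)
      .stopf("oob mode needs the training data (%d rows, got %d)",
             nrow(inbag), n)
    mask <- inbag == 0
    denom <- pmax(colSums(mask), 1L)
    use_tree <- colSums(mask) > 0
    base_acc_t <- colSums((base_pred == y_code) & mask) / denom
  } else {
    mask <- NULL
    denom <- rep(n, rf$num.trees)
    use_tree <- rep(TRUE, rf$num.trees)
    base_acc_t <- colMeans(base_pred == y_code)
  }
  set.seed(seed)
  imp <- numeric(p)
  for (r in seq_len(n_rep)) {
    for (start in seq(1, p, by = chunk)) {
      cols <- start:min(start + chunk - 1, p)
      rep_idx <- rep(seq_len(n), length(cols))
      big <- x[rep_idx, , drop = FALSE]
      for (k in seq_along(cols)) {
        rows <- (k - 1) * n + seq_len(n)
        big[rows, cols[k]] <- x[sample.int(n), cols[k]]
      }
      bigdf <- as.data.frame(big)
      names(bigdf) <- model$feature_names
      pred <- predict(rf, bigdf, predict.all = TRUE, num.threads = 1,
                      verbose = FALSE)$predictions
      correct <- pred == y_code[rep_idx]
      if (!is.null(mask)) correct <- correct & mask[rep_idx, , drop = FALSE]
      block <- rep(seq_along(cols), each = n)
      acc_bt <- rowsum(correct + 0, block) /
        matrix(denom, length(cols), length(denom), byrow = TRUE)
      drops <- sweep(-acc_bt, 2, base_acc_t, "+")
      imp[cols] <- imp[cols] + rowMeans(drops[, use_tree, drop = FALSE])
    }
  }
  setNames(imp / n_rep, colnames(x))
}

#' Vita-style variable selection
#'
#' Cross-validated permutation importance with a null distribution built by
#' mirroring the non-positive importances.  The data are split into
#' stratified folds; for each fold a forest is trained on the remaining
#' folds and permutation importance is computed on the held-out fold; the
#' fold-averaged importance of a truly uninformative feature is symmetric
#' around zero, so the observed non-positive values (and their mirror
#' images) estimate the null, yielding an empirical p-value per feature.
#' Features with `p < threshold` are retained.
#'
#' @param x feature matrix (samples x features).
#' @param y class labels.
#' @param n_folds cross-validation folds (default 5; reduced with a warning
#'   when the smallest class is smaller).
#' @param threshold selection p-value threshold (default 0.05).
#' @param num_trees trees per fold forest (default 500).
#' @param seed integer seed.
#' @return list with `selected` (feature names), `importance`, `p_value`.
#' @export
vita_select <- function(x, y, n_folds = 5, threshold = 0.05,
                        num_trees = 500, seed = 1) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) .stopf("vita selection needs >= 2 classes")
  n <- nrow(x)
  min_class <- min(table(y))
  if (n_folds > min_class) {
    n_folds <- max(2L, min_class)
    .warnf("reducing folds to %d (smallest class size)", n_folds)
  }
  set.seed(seed)
  fold <- integer(n)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  imp <- matrix(0, n_folds, ncol(x))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2) next
    fit <- fit_forest(x[tr, , drop = FALSE], y[tr], num_trees = num_trees,
                      seed = seed + f)
    imp[f, ] <- permutation_importance(fit, x[!tr, , drop = FALSE], y[!tr],
                                       seed = seed + 100 + f)
  }
  v <- colMeans(imp)
  names(v) <- colnames(x)
  nonpos <- v[v <= 0]
  if (length(nonpos) == 0) {
    .warnf("no non-positive importances: selecting all positive features")
    pv <- rep(0, length(v))
  } else {
    null_dist <- c(nonpos, -nonpos)
    pv <- vapply(v, function(vi) {
      (sum(null_dist >= vi) + 1) / (length(null_dist) + 1)
    }, 0)
  }
  names(pv) <- colnames(x)
  list(selected = colnames(x)[pv < threshold & v > 0],
       importance = v, p_value = pv, n_folds = n_folds)
}
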
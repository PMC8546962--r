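#' Classify samples by site or region with a seeded random forest
#'
#' One full modelling round: partition (stratified 70:30 split or
#' leave-one-vintage-out), optional vita variable selection on the training
#' set only (to avoid leakage into the test set), tuned/seeded forest fit,
#' evaluation on the test set, and casewise importance on the training set.
#'
#' @param x samples x features numeric matrix (ASV relative abundances for
#'   amplicon models, gene-attribute summaries for transcriptome models).
#' @param labels class label per sample (site or region).
#' @param scheme `"split70"` or `"lovo"`.
#' @param vintage,holdout_vintage vintage labels and held-out vintage for
#'   `"lovo"`.
#' @param vita run [vita_select()] on the training set first (default FALSE;
#'   used for transcriptome models).
#' @param num_trees forest size (default 10000).
#' @param tune tune hyperparameters by OOB error.
#' @param seed integer seed (drives partition, selection, and forest).
#' @param ... passed to [fit_forest()].
#' @return a `model_result`: `model`, `train`, `test`, `selected`,
#'   `confusion`, `accuracy`, `kappa`, `global_importance`,
#'   `casewise_importance`, `seed`, `scheme`, `target_levels`.
#' @export
classify_samples <- function(x, labels, scheme = c("split70", "lovo"),
                             vintage = NULL, holdout_vintage = NULL,
                             vita = FALSE, num_trees = 10000, tune = FALSE,
                             seed = 1, ...) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  part <- partition(labels, scheme, vintage = vintage,
                    holdout_vintage = holdout_vintage, seed = seed)
  x_tr <- x[part$train, , drop = FALSE]
  y_tr <- droplevels(labels[part$train])
  selected <- colnames(x)
  if (vita) {
    vs <- vita_select(x_tr, y_tr, seed = seed,
                      num_trees = max(200L, ceiling(num_trees / 20)))
    if (length(vs$selected) >= 2) selected <- vs$selected
  }
  fit <- fit_forest(x_tr[, selected, drop = FALSE], y_tr,
                    num_trees = num_trees, tune = tune, seed = seed, ...)
  ev <- evaluate(fit, x[part$test, selected, drop = FALSE], labels[part$test])
  cw <- casewise_importance(fit)
  structure(list(
    model = fit, train = part$train, test = part$test, selected = selected,
    confusion = ev$confusion, accuracy = ev$accuracy, kappa = ev$kappa,
    global_importance = fit$rf$variable.importance,
    casewise_importance = cw, seed = seed, scheme = scheme,
    target_levels = levels(labels)
  ), class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("model_result [%s]: accuracy %.3f, kappa %.3f, %d features\n",
              x$scheme, x$accuracy, x$kappa, length(x$selected)))
  invisible(x)
}

#' Consensus signature extraction across seeded models
#'
#' The core inference: variable selection and model fitting are repeated
#' with `S` different seeds; for each model the casewise importances are
#' averaged over the training fermentations of each class, features with a
#' positive class-average are retained, and the per-class retained gene sets
#' are intersected across all `S` models.  A gene qualifies for a class if
#' any of its five summary attributes qualifies (attributes of one gene are
#' strongly correlated).  The strict intersection makes the signature
#' robust to the forest's nondeterminism: only genes predictive in every
#' model survive.  An empty intersection is a valid outcome.
#'
#' @param features a [summarize_timeseries()] result, or a plain samples x
#'   features matrix (then `gene_of` maps feature to gene).
#' @param labels class label per fermentation (site or region); defaults to
#'   the named column of `features$fermentations`.
#' @param target `"site"` or `"region"` (used when `labels` is NULL).
#' @param scheme `"split70"` (per-seed random splits) or `"lovo"`.
#' @param S number of seeds (default 100).
#' @param num_trees forest size per model (default 10000).
#' @param vita run vita selection per seed (default TRUE).
#' @param holdout_vintage held-out vintage under `"lovo"`.
#' @param seed base seed; model s uses `seed + s`.
#' @param gene_of,attribute_of optional feature-to-gene / feature-to-attribute
#'   maps for matrix input.
#' @return a `signature_set`: per class, a data frame of qualifying genes
#'   with their best attribute and mean positive class-average importance
#'   across seeds; plus provenance (`S`, `scheme`, seeds).
#' @export
consensus_signature <- function(features, labels = NULL,
                                target = c("site", "region"),
                                scheme = c("split70", "lovo"), S = 100,
                                num_trees = 10000, vita = TRUE,
                                holdout_vintage = NULL, seed = 0,
                                gene_of = NULL, attribute_of = NULL) {
  scheme <- match.arg(scheme)
  target <- match.arg(target)
  if (S < 2) .stopf("consensus needs S >= 2 seeds")
  if (inherits(features, "fermentation_features")) {
    x <- features$x
    if (is.null(labels)) labels <- features$fermentations[[target]]
    vintage <- features$fermentations$vintage
    gene_of <- setNames(features$gene, colnames(x))
    attribute_of <- setNames(features$attribute, colnames(x))
  } else {
    x <- as.matrix(features)
    vintage <- NULL
    if (is.null(gene_of))
      gene_of <- setNames(colnames(x), colnames(x))
    if (is.null(attribute_of))
      attribute_of <- setNames(rep("value", ncol(x)), colnames(x))
  }
  if (ncol(x) == 0) .stopf("no features: cannot extract signatures")
  labels <- droplevels(as.factor(labels))
  classes <- levels(labels)
  kept <- setNames(vector("list", length(classes)), classes)      # gene sets
  imp_sum <- list()   # class -> feature -> running mean importance
  for (s in seq_len(S)) {
    res <- classify_samples(
      x, labels, scheme = scheme, vintage = vintage,
      holdout_vintage = holdout_vintage, vita = vita,
      num_trees = num_trees, seed = seed + s)
    cw <- res$casewise_importance
    y_tr <- labels[res$train]
    for (cl in classes) {
      rows <- which(y_tr == cl)
      cls_avg <- colMeans(cw[rows, , drop = FALSE], na.rm = TRUE)
      pos <- names(cls_avg)[cls_avg > 0 & !is.na(cls_avg)]
      genes_s <- unique(gene_of[pos])
      kept[[cl]] <- if (s == 1) genes_s else intersect(kept[[cl]], genes_s)
      key <- paste0(cl, "\r")
      prev <- imp_sum[[key]]
      cur <- cls_avg[cls_avg > 0]
      imp_sum[[key]] <- if (is.null(prev)) cur else {
        all_f <- union(names(prev), names(cur))
        out <- setNames(numeric(length(all_f)), all_f)
        out[names(prev)] <- prev
        out[names(cur)] <- out[names(cur)] + cur
        out
      }
    }
  }
  sig <- lapply(classes, function(cl) {
    genes <- kept[[cl]]
    if (length(genes) == 0)
      return(data.frame(gene = character(0), attribute = character(0),
                        mean_importance = numeric(0)))
    mi <- imp_sum[[paste0(cl, "\r")]] / S
    feats <- names(mi)[gene_of[names(mi)] %in% genes]
    best <- vapply(genes, function(g) {
      fg <- feats[gene_of[feats] == g]
      if (length(fg) == 0) return(NA_character_)
      fg[which.max(mi[fg])]
    }, "")
    data.frame(gene = genes,
               attribute = unname(attribute_of[best]),
               mean_importance = unname(mi[best]),
               stringsAsFactors = FALSE)
  })
  names(sig) <- classes
  structure(list(signatures = sig, S = S, scheme = scheme,
                 seeds = seed + seq_len(S), target = target),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  sizes <- vapply(x$signatures, nrow, 0L)
  cat(sprintf("signature_set [%s, S = %d]: %d classes, %d genes total\n",
              x$scheme, x$S, length(sizes),
              length(unique(unlist(lapply(x$signatures, `[[`, "gene"))))))
  invisible(x)
}

#' Genes in a signature set (union over classes)
#' @param sig a `signature_set`.
#' @return character vector of gene ids.
#' @export
signature_genes <- function(sig) {
  unique(unlist(lapply(sig$signatures, `[[`, "gene"), use.names = FALSE))
}

#' Score a signature set against a study's ground truth
#'
#' Sensitivity is the fraction of planted site-informative genes recovered
#' (union over classes); the null-inclusion rate is the fraction of
#' not-planted genes that entered any signature.
#'
#' @param sig a `signature_set`.
#' @param truth a synthetic study's `truth` record.
#' @return list with `sensitivity`, `null_inclusion`, `n_recovered`.
#' @export
score_signature <- function(sig, truth) {
  found <- signature_genes(sig)
  planted <- truth$site_genes
  nulls <- truth$null_genes
  list(
    sensitivity = if (length(planted)) mean(planted %in% found) else NA_real_,
    null_inclusion = if (length(nulls)) mean(nulls %in% found) else NA_real_,
    n_recovered = sum(planted %in% found)
  )
}

#' Attribute importance to organisms
#'
#' Percent of total (non-negative) importance attributable to each organism:
#' negative importances are truncated to zero, summed per organism, and
#' expressed as a percentage of the grand total (sums to 100).
#'
#' @param importance named numeric vector (names are features `<gene>` or
#'   `<gene>|<attribute>`).
#' @param organism_map named character vector mapping gene to organism.
#' @return named numeric vector of percentages.
#' @export
organism_attribution <- function(importance, organism_map) {
  genes <- sub("\\|.*$", "", names(importance))
  org <- organism_map[genes]
  if (anyNA(org)) .stopf("organism unknown for gene '%s'",
                         genes[is.na(org)][1])
  pos <- pmax(importance, 0)
  tot <- sum(pos)
  if (tot == 0) {
    .warnf("all importances non-positive: attribution undefined")
    return(setNames(rep(NA_real_, length(unique(org))), unique(org)))
  }
  s <- rowsum(pos, org)
  setNames(as.numeric(s) / tot * 100, rownames(s))
}
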
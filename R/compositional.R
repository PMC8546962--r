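#' Relative abundance (total-sum scaling)
#'
#' Divides each sample's counts by its library size, so every sample column
#' sums to one.  Sequencing counts only carry compositional information; all
#' regression and random-forest inputs in this package are relative
#' abundances, not raw counts.
#'
#' @param x a `count_table` or a features x samples numeric matrix.
#' @return a features x samples matrix of proportions.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  tot <- colSums(m)
  if (any(tot <= 0))
    .stopf("sample '%s' has zero total count", colnames(m)[which(tot <= 0)[1]])
  sweep(m, 2, tot, "/")
}

#' Centered log-ratio transform
#'
#' Maps each sample's composition to unconstrained space via
#' `clr(x)_i = log(x_i / g(x))` with `g` the geometric mean, after replacing
#' zeros according to `pseudocount`:
#' \describe{
#'   \item{`"multiplicative"`}{(default) zeros in the relative-abundance
#'     matrix are replaced by half the smallest nonzero relative abundance in
#'     the table, and nonzero entries are shrunk multiplicatively so each
#'     sample still sums to one.}
#'   \item{`"add_one"`}{one pseudo-read is added to every count before
#'     closing to proportions.}
#' }
#' Each CLR vector sums to zero, and the transform is invariant to scaling a
#' sample's counts by any positive constant.
#'
#' @param x a `count_table` or features x samples count matrix.
#' @param pseudocount zero-replacement policy, see Details.
#' @return features x samples matrix of CLR values (columns sum to 0).
#' @export
clr_transform <- function(x, pseudocount = c("multiplicative", "add_one")) {
  pseudocount <- match.arg(pseudocount)
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (any(m < 0)) .stopf("counts must be non-negative")
  if (pseudocount == "add_one") {
    p <- relative_abundance(m + 1)
  } else {
    p <- relative_abundance(m)
    if (any(p == 0)) {
      delta <- min(p[p > 0]) / 2
      nz <- colSums(p == 0)
      # multiplicative replacement: zeros -> delta, nonzeros rescaled so
      # columns still sum to one
      p <- sweep(p, 2, 1 - delta * nz, "*")
      p[m == 0] <- delta
    }
  }
  lp <- log(p)
  sweep(lp, 2, colMeans(lp), "-")
}

#' Distance matrices
#'
#' A `dist_matrix` wraps a symmetric non-negative matrix with zero diagonal
#' and a metric name; it is the common currency of all permutation tests.
#'
#' @param values symmetric numeric matrix with dimnames.
#' @param metric metric name, e.g. `"aitchison"`, `"euclidean"`,
#'   `"haversine_km"`.
#' @return an object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, metric = "euclidean") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) .stopf("distance matrix must be square")
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    .stopf("distance matrix is not symmetric")
  if (any(abs(diag(values)) > 0)) .stopf("distance matrix diagonal must be 0")
  if (any(values < 0, na.rm = TRUE)) .stopf("distances must be non-negative")
  structure(list(sample_ids = rownames(values),
                 values = values, metric = metric),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix [%s]: %d samples\n", x$metric, length(x$sample_ids)))
  invisible(x)
}

#' @export
as.dist.dist_matrix <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$values, diag = diag, upper = upper)

#' Aitchison distance
#'
#' Euclidean distance between samples in CLR space.  Accepts either a CLR
#' matrix (features x samples, as returned by [clr_transform()]) or a
#' `count_table`, in which case the CLR transform is applied first.
#'
#' @param x CLR matrix or `count_table`.
#' @param ... passed to [clr_transform()] when `x` is a count table.
#' @return a [dist_matrix()] with metric `"aitchison"`.
#' @export
aitchison_distance <- function(x, ...) {
  clr <- if (inherits(x, "count_table")) clr_transform(x, ...) else as.matrix(x)
  d <- as.matrix(dist(t(clr), method = "euclidean"))
  dist_matrix(d, metric = "aitchison")
}

#' Core microbiome
#'
#' The features present above an abundance floor in at least a prevalence
#' fraction of samples; defaults are 1% relative abundance in 90% of samples,
#' assessed per sample.
#'
#' @param x a `count_table`.
#' @param prevalence minimum fraction of samples (default 0.90).
#' @param abundance minimum relative abundance within a sample (default 0.01).
#' @return character vector of core feature ids.
#' @export
core_microbiome <- function(x, prevalence = 0.90, abundance = 0.01) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (nrow(m) == 0L || ncol(m) == 0L) return(character(0))
  p <- relative_abundance(m)
  frac <- rowMeans(p >= abundance)
  rownames(m)[frac >= prevalence]
}

#' Alpha diversity
#'
#' Per-sample Shannon entropy (natural log, reported in nats) or
#' bias-corrected Chao1 richness
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and `F2` are the numbers
#' of singleton and doubleton features; the bias-corrected form stays defined
#' when no doubletons are observed.
#'
#' @param x a `count_table` or features x samples count matrix.
#' @param metric `"shannon"` or `"chao1"`.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(x, metric = c("shannon", "chao1")) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (any(colSums(m) == 0))
    .stopf("sample '%s' has zero total count",
           colnames(m)[which(colSums(m) == 0)[1]])
  if (metric == "shannon") {
    return(vegan::diversity(t(m), index = "shannon"))
  }
  apply(m, 2, function(v) {
    s_obs <- sum(v > 0)
    f1 <- sum(v == 1)
    f2 <- sum(v == 2)
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  })
}
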
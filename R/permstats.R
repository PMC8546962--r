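#' @title Permutation-based community statistics
#' @description ANOSIM, PERMANOVA and Mantel tests computed from their
#'   definitions on a [dist_matrix()], with seeded Monte-Carlo permutation
#'   p-values or exhaustive enumeration (`n_perm = "exact"`) for small n.
#'   P-values use `(b + 1) / (m + 1)` with `b` the number of permuted
#'   statistics at least as large as the observed one, so they are never zero.
#' @name permstats
NULL

.as_dist_values <- function(d) {
  if (inherits(d, "dist_matrix")) return(d$values)
  if (inherits(d, "dist")) return(as.matrix(d))
  as.matrix(d)
}

.lower_idx <- function(n) {
  lt <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(ri = lt[, 1], ci = lt[, 2])
}

.check_groups <- function(groups, n) {
  groups <- as.factor(groups)
  if (length(groups) != n) .stopf("groups must have one label per sample")
  if (nlevels(droplevels(groups)) < 2) .stopf("need at least 2 groups")
  sizes <- table(droplevels(groups))
  if (any(sizes < 2))
    .stopf("group '%s' has fewer than 2 samples", names(sizes)[sizes < 2][1])
  droplevels(groups)
}

# All permutations of 1..n (identity first), via permute::allPerms.
.all_perms <- function(n) {
  rbind(seq_len(n), as.matrix(permute::allPerms(n, control = permute::how())))
}

.perm_pvalue <- function(stat_obs, stat_perm, exact, eps = 1e-9) {
  b <- sum(stat_perm >= stat_obs - eps)
  if (exact) b / length(stat_perm) else (b + 1) / (length(stat_perm) + 1)
}

.perm_result <- function(method, statistic, p, n_perm, seed,
                         effect_partition = NULL, flag = NULL, extra = list()) {
  structure(c(list(method = method, statistic = statistic, p_value = p,
                   n_permutations = n_perm, effect_partition = effect_partition,
                   seed = seed, flag = flag), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s permutations)%s\n",
              x$method, x$statistic, x$p_value,
              format(x$n_permutations),
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  if (!is.null(x$effect_partition))
    cat("  R2:", paste(sprintf("%s = %.4f", names(x$effect_partition),
                               x$effect_partition), collapse = ", "), "\n")
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based comparison of between- versus within-group dissimilarities:
#' `R = (mean rank between - mean rank within) / (M / 2)` with
#' `M = n (n - 1) / 2` pairwise distances and average ranks for ties.
#' `R` lies in `[-1, 1]`; values near 1 indicate that samples within a group
#' are more similar than samples from different groups.  Significance is
#' assessed by permuting group labels.
#'
#' @param d a [dist_matrix()] (or square matrix / `dist`).
#' @param groups group label per sample (site, region, vintage, ...).
#' @param n_perm number of permutations (default 9999), or `"exact"` to
#'   enumerate all `n!` label permutations.
#' @param seed integer seed for the permutation stream.
#' @return a `perm_test` with elements `statistic` (R), `p_value`,
#'   `n_permutations`, `seed`.
#' @export
anosim <- function(d, groups, n_perm = 9999, seed = NULL) {
  v <- .as_dist_values(d)
  n <- nrow(v)
  groups <- .check_groups(groups, n)
  li <- .lower_idx(n)
  rv <- rank(v[lower.tri(v)])
  M <- n * (n - 1) / 2
  g <- as.integer(groups)
  stat_fun <- function(gp) {
    w <- gp[li$ri] == gp[li$ci]
    (mean(rv[!w]) - mean(rv[w])) / (M / 2)
  }
  obs <- stat_fun(g)
  exact <- identical(n_perm, "exact")
  if (exact) {
    perms <- .all_perms(n)
    stat_perm <- apply(perms, 1, function(p) stat_fun(g[p]))
    m <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    m <- as.integer(n_perm)
    stat_perm <- vapply(seq_len(m), function(i) stat_fun(sample(g)), 0)
  }
  .perm_result("ANOSIM", obs, .perm_pvalue(obs, stat_perm, exact), m, seed)
}

.permanova_ss <- function(d2v, gp, ri, ci, N) {
  ss_t <- sum(d2v) / N
  same <- gp[ri] == gp[ci]
  n_g <- tabulate(gp)
  if (!any(same)) return(c(ss_t = ss_t, ss_w = 0))
  sums <- rowsum(d2v[same], gp[ri][same])
  ss_w <- sum(sums / n_g[as.integer(rownames(sums))])
  c(ss_t = ss_t, ss_w = ss_w)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor partitioning of the squared-distance sums of squares:
#' `SS_T = sum(d_ij^2) / N` over all pairs, `SS_W = sum_g sum(d_ij^2) / n_g`
#' over within-group pairs, pseudo-F
#' `((SS_T - SS_W) / (a - 1)) / (SS_W / (N - a))`, and
#' `R^2 = (SS_T - SS_W) / SS_T`.  Significance by permutation of group
#' labels.  When every group collapses to identical points (`SS_W = 0`) the
#' statistic is reported as `Inf` with flag `"maximal_F"`.
#'
#' @inheritParams anosim
#' @return a `perm_test` with `statistic` (pseudo-F), `p_value`, and
#'   `effect_partition` holding the term's `R2`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = NULL) {
  v <- .as_dist_values(d)
  n <- nrow(v)
  groups <- .check_groups(groups, n)
  a <- nlevels(groups)
  li <- .lower_idx(n)
  d2v <- v[lower.tri(v)]^2
  g <- as.integer(groups)
  stat_fun <- function(gp) {
    ss <- .permanova_ss(d2v, gp, li$ri, li$ci, n)
    if (ss[["ss_w"]] == 0) return(Inf)
    ((ss[["ss_t"]] - ss[["ss_w"]]) / (a - 1)) / (ss[["ss_w"]] / (n - a))
  }
  obs <- stat_fun(g)
  ss <- .permanova_ss(d2v, g, li$ri, li$ci, n)
  r2 <- (ss[["ss_t"]] - ss[["ss_w"]]) / ss[["ss_t"]]
  exact <- identical(n_perm, "exact")
  if (exact) {
    perms <- .all_perms(n)
    stat_perm <- apply(perms, 1, function(p) stat_fun(g[p]))
    m <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    m <- as.integer(n_perm)
    stat_perm <- vapply(seq_len(m), function(i) stat_fun(sample(g)), 0)
  }
  .perm_result("PERMANOVA", obs, .perm_pvalue(obs, stat_perm, exact), m, seed,
               effect_partition = c(group = r2),
               flag = if (!is.finite(obs)) "maximal_F" else NULL,
               extra = list(ss_total = ss[["ss_t"]], ss_within = ss[["ss_w"]]))
}

#' Mantel test
#'
#' Correlation between two distance matrices over the same samples, computed
#' on the strictly-lower-triangle vectors (Spearman by default, average ranks
#' for ties).  Permutations jointly permute rows and columns of the second
#' matrix; missing entries are dropped pairwise.  A constant matrix leaves the
#' correlation undefined: the result carries flag `"degenerate"` with an `NA`
#' statistic rather than propagating `NaN`.
#'
#' @param d1,d2 [dist_matrix()] objects (or square matrices) over the same
#'   samples in the same order.
#' @param method correlation method, `"spearman"` (default) or `"pearson"`.
#' @inheritParams anosim
#' @return a `perm_test` with `statistic` (Mantel r).
#' @export
mantel <- function(d1, d2, method = c("spearman", "pearson"),
                   n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  v1 <- .as_dist_values(d1)
  v2 <- .as_dist_values(d2)
  if (!all(dim(v1) == dim(v2)))
    .stopf("distance matrices have different sizes")
  if (inherits(d1, "dist_matrix") && inherits(d2, "dist_matrix") &&
      !identical(d1$sample_ids, d2$sample_ids))
    .stopf("distance matrices are over different samples or orders")
  n <- nrow(v1)
  lt <- lower.tri(v1)
  x1 <- v1[lt]
  x2 <- v2[lt]
  ok <- complete.cases(x1, x2)
  if (sd(x1[ok]) == 0 || sd(x2[ok]) == 0)
    return(.perm_result(paste0("Mantel (", method, ")"), NA_real_, NA_real_,
                        0L, seed, flag = "degenerate"))
  has_na <- anyNA(v1[lt]) || anyNA(v2[lt])
  if (!has_na && method == "spearman") {
    # ranks are permutation-equivariant: pre-rank both matrices once and use
    # Pearson correlation of the rank vectors for every permutation
    r1m <- v1; r1m[lt] <- rank(x1); r1m <- .symmetrize_lower(r1m)
    r2m <- v2; r2m[lt] <- rank(x2); r2m <- .symmetrize_lower(r2m)
    x1 <- r1m[lt]
    stat_fun <- function(p) cor(x1, r2m[p, p][lt])
    obs <- cor(x1, r2m[lt])
  } else {
    stat_fun <- function(p) cor(x1, v2[p, p][lt], method = method,
                                use = "pairwise.complete.obs")
    obs <- cor(x1, x2, method = method, use = "pairwise.complete.obs")
  }
  exact <- identical(n_perm, "exact")
  if (exact) {
    perms <- .all_perms(n)
    stat_perm <- apply(perms, 1, stat_fun)
    m <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    m <- as.integer(n_perm)
    stat_perm <- vapply(seq_len(m), function(i) stat_fun(sample.int(n)), 0)
  }
  .perm_result(paste0("Mantel (", method, ")"), obs,
               .perm_pvalue(obs, stat_perm, exact), m, seed)
}

.symmetrize_lower <- function(m) {
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  diag(m) <- 0
  m
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a vector of permutation p-values; results are
#' conventionally reported at an FDR threshold of 0.1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and names.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) .stopf("p-values must lie in (0, 1]")
  p.adjust(p, method = "fdr")
}

#' Nonmetric multidimensional scaling
#'
#' Kruskal stress-1 NMDS of a distance matrix (global monotone regression via
#' `vegan::monoMDS`), best configuration over `n_restarts` starts (the first
#' from metric scaling, the rest random).  Coordinates are centered and
#' rotated to principal axes with a fixed sign convention so output is
#' orientation-stable across runs.
#'
#' @param d a [dist_matrix()].
#' @param k target dimensionality (default 2).
#' @param n_restarts number of starts (default 20).
#' @param seed integer seed.
#' @param maxit maximum iterations per start.
#' @return an `nmds_result` with `coordinates` (samples x k), `stress`,
#'   `converged`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = NULL, maxit = 500) {
  v <- .as_dist_values(d)
  n <- nrow(v)
  if (n < k + 1) .stopf("NMDS needs at least k + 1 = %d samples", k + 1)
  if (!is.null(seed)) set.seed(seed)
  dd <- stats::as.dist(v)
  best <- NULL
  for (i in seq_len(n_restarts)) {
    fit <- if (i == 1) {
      vegan::monoMDS(dd, k = k, model = "global", maxit = maxit,
                     smin = 1e-6, sratmax = 1 - 1e-6)
    } else {
      y0 <- matrix(runif(n * k, -1, 1), n, k)
      vegan::monoMDS(dd, y = y0, k = k, model = "global", maxit = maxit,
                     smin = 1e-6, sratmax = 1 - 1e-6)
    }
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  if (n > 1) {
    pc <- prcomp(pts, center = FALSE)
    pts <- pc$x[, seq_len(k), drop = FALSE]
  }
  for (j in seq_len(ncol(pts))) {
    s <- sign(pts[which.max(abs(pts[, j])), j])
    if (s < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(v)
  colnames(pts) <- paste0("NMDS", seq_len(ncol(pts)))
  structure(list(coordinates = pts, stress = best$stress,
                 converged = best$icause != 1L, n_restarts = n_restarts),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d samples in %d dims, stress = %.4g, converged = %s\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress, x$converged))
  invisible(x)
}

#' Great-circle (haversine) distance matrix
#'
#' Pairwise great-circle distances between sites, in km, using the haversine
#' formula with the IUGG mean Earth radius 6371.0088 km.
#'
#' @param coords data frame or matrix with columns `latitude_deg` and
#'   `longitude_deg` (or two unnamed columns in that order), one row per site.
#' @return a [dist_matrix()] with metric `"haversine_km"`.
#' @export
haversine_matrix <- function(coords) {
  coords <- as.data.frame(coords)
  if (all(c("latitude_deg", "longitude_deg") %in% names(coords))) {
    lat <- coords$latitude_deg
    lon <- coords$longitude_deg
  } else {
    lat <- coords[[1]]
    lon <- coords[[2]]
  }
  if (any(abs(lat) > 90)) .stopf("latitude out of range [-90, 90]")
  if (any(abs(lon) > 180)) .stopf("longitude out of range [-180, 180]")
  # geosphere::distHaversine uses r = 6378137 m; haversine distance is
  # proportional to the radius, so rescale to the 6371.0088 km mean radius
  d_m <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine)
  d_km <- d_m * (6371.0088 / 6378.137) / 1000
  ids <- if ("site" %in% names(coords)) coords$site else rownames(coords)
  if (!is.null(ids)) rownames(d_km) <- colnames(d_km) <- ids
  d_km <- (d_km + t(d_km)) / 2
  diag(d_km) <- 0
  dist_matrix(d_km, metric = "haversine_km")
}

#' Scale and center covariate columns
#'
#' Standardizes each column to mean 0 and standard deviation 1, as done
#' before combining disparate measurement types into one distance matrix.
#' Constant columns cannot be standardized and are dropped with a warning.
#'
#' @param m numeric matrix or data frame.
#' @return standardized numeric matrix.
#' @export
scale_center <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2, sd, na.rm = TRUE)
  const <- is.na(sds) | sds == 0
  if (any(const)) {
    .warnf("dropping constant column(s): %s",
           paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  out <- scale(m, center = TRUE, scale = TRUE)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}
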
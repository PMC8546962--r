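# Brute-force oracles for the permutation statistics, written from the
# definitions with explicit loops and kept independent of the package's
# vectorized implementations.

# All permutations of 1..n as a matrix (recursive construction).
perms_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_all(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

brute_anosim_R <- function(d, g) {
  n <- nrow(d)
  pairs <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    pairs <- rbind(pairs, c(d[i, j], g[i] == g[j]))
  r <- rank(pairs[, 1])
  rw <- mean(r[pairs[, 2] == 1])
  rb <- mean(r[pairs[, 2] == 0])
  M <- n * (n - 1) / 2
  (rb - rw) / (M / 2)
}

brute_permanova <- function(d, g) {
  n <- nrow(d)
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    s <- 0
    if (length(idx) >= 2)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + d[idx[a], idx[b]]^2
    ss_w <- ss_w + s / length(idx)
  }
  a <- length(unique(g))
  list(ss_t = ss_t, ss_w = ss_w,
       F = ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a)),
       R2 = (ss_t - ss_w) / ss_t)
}

brute_mantel_r <- function(d1, d2) {
  v1 <- v2 <- numeric(0)
  n <- nrow(d1)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    v1 <- c(v1, d1[j, i]); v2 <- c(v2, d2[j, i])
  }
  cor(rank(v1), rank(v2))
}

# Exhaustive-enumeration p-values over all n! label arrangements,
# p = (# permuted statistics >= observed) / n!, same >= convention
# (tolerance 1e-9) as the implementation.
brute_exact_p <- function(stat_fun, n) {
  pm <- perms_all(n)
  stats <- apply(pm, 1, stat_fun)
  obs <- stat_fun(seq_len(n))
  mean(stats >= obs - 1e-9)
}

# Small random Euclidean distance matrix with sample names.
random_dist <- function(n, p = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  rownames(x) <- paste0("s", seq_len(n))
  dist_matrix(as.matrix(dist(x)))
}

# Tiny count table builder.
toy_table <- function(counts, marker = "16S", taxonomy = NULL, ...) {
  count_table(counts, marker, taxonomy = taxonomy, ...)
}
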
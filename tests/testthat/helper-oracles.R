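# Independent oracles and small fixture builders shared across tests.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n, n1) group labelings of the pooled data. Independent of wilcox.test:
# builds the permutation distribution of the Mann-Whitney U statistic
# directly.
enumeration_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(length(pooled), n1)
  u_all <- apply(labelings, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Single-linkage clustering oracle: connected components of the graph with
# an edge between every pair of peaks closer than tol * min(mz). On
# instances whose groups are tight (spread << tol) and mutually far apart
# (gaps >> tol) every single-linkage variant yields these components.
components_cluster_oracle <- function(mz, tolerance_frac) {
  n <- length(mz)
  adj <- abs(outer(mz, mz, "-")) < tolerance_frac * outer(mz, mz, pmin)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# Random clustering instance: groups of peaks with within-group spread far
# below the tolerance and between-group gaps far above it, pooled over
# distinct samples so no same-sample conflicts arise.
make_cluster_instance <- function(n_peaks = 30L, tolerance_frac = 0.003) {
  n_groups <- sample(3:8, 1L)
  centers <- sort(runif(n_groups, 1000, 19000))
  # enforce gaps > 4x tolerance
  ok <- c(TRUE, diff(centers) > 4 * tolerance_frac * centers[-n_groups])
  centers <- centers[ok]
  n_groups <- length(centers)
  sizes <- as.integer(tabulate(sample.int(n_groups, n_peaks, replace = TRUE),
                               nbins = n_groups))
  mz <- unlist(lapply(seq_len(n_groups), function(g) {
    if (sizes[g] == 0L) return(numeric())
    centers[g] + runif(sizes[g], -0.2, 0.2) * tolerance_frac * centers[g]
  }))
  keep <- length(mz)
  data.frame(mz = mz,
             sample = paste0("s", seq_len(keep)),
             intensity = runif(keep, 10, 500),
             truth = rep(seq_len(n_groups), sizes))
}

# Brute-force Youden scan: every candidate threshold x both orientations,
# straight confusion counting.
brute_force_best_J <- function(values, labels) {
  is_case <- labels == "case"
  cand <- sort(unique(values))
  cand <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1)
  best <- -Inf
  for (thr in cand) for (high_is_case in c(TRUE, FALSE)) {
    pred <- if (high_is_case) values > thr else values < thr
    J <- sum(pred & is_case) / sum(is_case) +
      sum(!pred & !is_case) / sum(!is_case) - 1
    best <- max(best, J)
  }
  best
}

# A tiny well-separated two-group feature matrix (samples x features).
toy_separable_matrix <- function(n_per_group = 6L, gap = 10, sd = 0.1,
                                 seed = 42L) {
  set.seed(seed)
  x <- cbind(c(rnorm(n_per_group, gap, sd), rnorm(n_per_group, -gap, sd)),
             rnorm(2 * n_per_group))
  colnames(x) <- c("1699.00", "3038.00")
  rownames(x) <- paste0("s", seq_len(2 * n_per_group))
  list(x = x, labels = rep(c("case", "control"), each = n_per_group))
}

# LOOCV accuracy by exhaustive search over all feature pairs.
exhaustive_best_pair_fitness <- function(x, labels, spec) {
  pairs <- utils::combn(ncol(x), 2L)
  max(apply(pairs, 2L, function(ij)
    loocv(x[, ij, drop = FALSE], labels, spec)$accuracy))
}
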
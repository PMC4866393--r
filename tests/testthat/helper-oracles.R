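# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and vectorized shortcuts) so that oracle-equivalence tests
# compare two genuinely different routes to the same quantity.

# Pairwise Pearson correlation between rows, double loop.
naive_row_cor <- function(m) {
  n <- nrow(m)
  C <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- m[i, ]; xj <- m[j, ]
    sxi <- sd(xi); sxj <- sd(xj)
    C[i, j] <- if (sxi == 0 || sxj == 0) NA_real_ else
      sum((xi - mean(xi)) * (xj - mean(xj))) / ((length(xi) - 1) * sxi * sxj)
  }
  C
}

# 1 - Pearson distance between flattened upper triangles, double loop.
naive_matrix_distance <- function(mats) {
  k <- length(mats)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- mats[[i]][upper.tri(mats[[i]])]
    b <- mats[[j]][upper.tri(mats[[j]])]
    d[i, j] <- 1 - cor(a, b)
  }
  diag(d) <- 0
  d
}

# Topological overlap, triple loop.
naive_tom <- function(D) {
  D <- unclass(D)
  n <- nrow(D)
  k <- rowSums(D)
  TOM <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + D[i, u] * D[u, j]
    TOM[i, j] <- (l + D[i, j]) / (min(k[i], k[j]) + 1 - D[i, j])
  }
  dimnames(TOM) <- dimnames(D)
  TOM
}

# UPGMA agglomeration from scratch; returns the cophenetic distance matrix
# (the canonical representation-independent summary of the merge history).
naive_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  cd <- function(A, B) mean(D[A, B])
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      dd <- cd(clusters[[idx[a]]], clusters[[idx[b]]])
      if (dd < bestd) { bestd <- dd; best <- c(idx[a], idx[b]) }
    }
    A <- clusters[[best[1]]]; B <- clusters[[best[2]]]
    coph[A, B] <- bestd; coph[B, A] <- bestd
    clusters[[length(clusters) + 1]] <- c(A, B)
    active[best] <- FALSE
    active[length(clusters)] <- TRUE
  }
  coph
}

# Step-up FDR, literal textbook loop.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Upper-tail hypergeometric by direct enumeration of the pmf.
naive_hyper_tail <- function(q, K, N, m) {
  ks <- max(0, q):min(K, m)
  sum(choose(K, ks) * choose(N - K, m - ks)) / choose(N, m)
}

# Internal helpers reached through the namespace (tests run against the
# installed package, where only exports are attached).
row_cor_public <- function(m) coexshift:::row_cor(m)
upper_tri_mean_public <- function(m) coexshift:::upper_tri_mean(m, na.rm = TRUE)
same_partition_public <- function(s, a, b) coexshift:::same_partition(s, a, b)

# Small labelled expression fixture: deterministic values, two windows.
toy_expression <- function(n_genes = 3, n_regions = 2, n_tp = 1,
                           seed = 42) {
  set.seed(seed)
  sim <- coexshift::simulate_expression(
    list(coexshift::module_spec(n_genes, "background")),
    n_regions = n_regions, n_timepoints_per_window = n_tp,
    region_effect_sd = 0.2, seed = seed)
  sim$expression
}
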
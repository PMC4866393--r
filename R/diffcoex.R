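# Differential coexpression core: per-condition correlation matrices,
# signed-squared-correlation adjacency difference, scale-free fit index,
# topological overlap, and the module rewiring statistics.

#' Pearson coexpression matrix of one stratum
#'
#' @param E_stratum an [expression_matrix()] with >= 3 samples.
#' @return symmetric gene x gene correlation matrix of class
#'   `CoexpressionMatrix`, diagonal 1. Genes constant within the stratum
#'   yield `NA` rows/columns and are recorded in the `constant_genes`
#'   attribute.
#' @export
coexpression <- function(E_stratum) {
  stopifnot(inherits(E_stratum, "ExpressionMatrix"))
  if (ncol(E_stratum$values) < 3)
    stop("coexpression needs at least 3 samples")
  v <- matrixStats_rowVars(E_stratum$values)
  const <- gene_ids(E_stratum)[v == 0]
  C <- row_cor(E_stratum$values)
  structure(C, constant_genes = const,
            class = c("CoexpressionMatrix", "matrix"))
}

# Pearson correlation between the rows of m via standardization +
# tcrossprod (BLAS); constant rows give NA, matching stats::cor.
row_cor <- function(m) {
  n <- ncol(m)
  s <- sqrt(matrixStats_rowVars(m))
  x <- (m - rowMeans(m)) / s
  x[s == 0, ] <- NA_real_
  C <- tcrossprod(x) / (n - 1)
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- ifelse(s == 0, NA_real_, 1)
  C
}

#' Differential-coexpression adjacency between two conditions
#'
#' Soft-thresholded absolute difference of the signed squared correlations:
#' `d_ij = (0.5 * |sign(c1) c1^2 - sign(c2) c2^2|)^(beta/2)`. The 1/2
#' normalization keeps d in \[0, 1\] (the raw difference spans \[-2, 2\]);
#' beta = 6 is the default soft threshold, chosen to approximate a
#' scale-free degree distribution (see [scale_free_fit()]).
#'
#' @param C_pre,C_post `CoexpressionMatrix` objects over the same genes.
#' @param beta even positive integer soft-threshold exponent (default 6).
#' @return symmetric matrix of class `DiffAdjacency`, entries in \[0, 1\],
#'   zero diagonal; carries `beta` as an attribute.
#' @export
adjacency_difference <- function(C_pre, C_post, beta = 6) {
  if (!identical(dim(C_pre), dim(C_post)) ||
      !identical(rownames(C_pre), rownames(C_post)))
    stop("mismatched gene sets between conditions")
  stopifnot(beta > 0, beta %% 2 == 0)
  C_pre <- unclass(C_pre); C_post <- unclass(C_post)
  s1 <- sign(C_pre) * C_pre^2
  s2 <- sign(C_post) * C_post^2
  D <- (0.5 * abs(s1 - s2))^(beta / 2)
  diag(D) <- 0
  structure(D, beta = beta, class = c("DiffAdjacency", "matrix"))
}

#' Scale-free topology fit index of an adjacency matrix
#'
#' Connectivities `k_i = sum_j d_ij` are binned into `n_bins` equal-width
#' bins; the fit index is the R^2 of regressing log10(frequency) on
#' log10(mean k) over occupied bins, the usual check that a soft threshold
#' yields an approximately power-law degree distribution.
#'
#' @param D a `DiffAdjacency` (or any nonnegative symmetric matrix).
#' @param n_bins number of connectivity bins (default 10).
#' @return scalar R^2 in \[0, 1\].
#' @export
scale_free_fit <- function(D, n_bins = 10) {
  k <- rowSums(unclass(D), na.rm = TRUE)
  if (length(unique(k)) < 2) stop("all connectivities identical")
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  meank <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & meank > 0
  if (sum(keep) < 2) stop("fewer than 2 occupied bins with positive k")
  fit <- stats::lm(log10(freq[keep]) ~ log10(meank[keep]))
  unname(summary(fit)$r.squared)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u d_iu d_uj + d_ij) / (min(k_i, k_j) + 1 - d_ij)` for
#' i != j and 1 on the diagonal: similarity combining the direct adjacency
#' with the shared neighbourhood. Computed in column blocks so the memory
#' high-water mark stays near two n x n matrices even at >= 20,000 genes.
#'
#' @param D a `DiffAdjacency`.
#' @param block_size columns per block (default 2000).
#' @return symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
topological_overlap <- function(D, block_size = 2000) {
  A <- unclass(D)
  n <- nrow(A)
  k <- rowSums(A)
  TOM <- matrix(0, n, n, dimnames = dimnames(A))
  for (start in seq(1, n, by = block_size)) {
    cols <- start:min(start + block_size - 1, n)
    L <- A %*% A[, cols, drop = FALSE]
    kmin <- pmin(matrix(k, n, length(cols)),
                 matrix(k[cols], n, length(cols), byrow = TRUE))
    TOM[, cols] <- (L + A[, cols, drop = FALSE]) /
      (kmin + 1 - A[, cols, drop = FALSE])
  }
  diag(TOM) <- 1
  TOM
}

#' Average within-module correlation change between conditions
#'
#' delta = mean upper-triangle correlation (condition 2) minus the same in
#' condition 1, the per-module rewiring effect size.
#'
#' @param E_pre,E_post [expression_matrix()] strata (>= 3 samples each).
#' @param module_genes character vector of >= 2 gene ids.
#' @return list with `n_genes`, `mean_r_pre`, `mean_r_post`, `delta`.
#' @export
rewiring_statistic <- function(E_pre, E_post, module_genes) {
  stopifnot(length(module_genes) >= 2)
  module_genes <- as.character(module_genes)
  r1 <- mean_module_cor(E_pre$values[module_genes, , drop = FALSE])
  r2 <- mean_module_cor(E_post$values[module_genes, , drop = FALSE])
  list(n_genes = length(module_genes), mean_r_pre = r1, mean_r_post = r2,
       delta = r2 - r1)
}

mean_module_cor <- function(m) {
  if (ncol(m) < 3) stop("stratum has fewer than 3 samples")
  upper_tri_mean(row_cor(m), na.rm = TRUE)
}

#' Permutation significance of a module's correlation change
#'
#' The null permutes the condition (window) labels across the pooled
#' samples, preserving the two stratum sizes; each permutation recomputes
#' delta. This preserves every gene's marginal distribution and tests
#' exactly the condition-dependence of the correlation structure. A
#' value-shuffle null (independently permuting each gene's values, which
#' destroys all correlation) is available via `scheme = "value"`.
#'
#' @param E_both pooled [expression_matrix()] holding both windows.
#' @param module_genes character vector of >= 2 gene ids.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed (a per-module stream is derived from it).
#' @param scheme `"label"` (default) or `"value"`.
#' @return list of class `ModuleRewiringStat` with the
#'   [rewiring_statistic()] fields plus two-sided `p` (resolution
#'   `1/(n_perm+1)`), `n_perm` and `scheme`.
#' @export
rewiring_permutation_test <- function(E_both, module_genes, n_perm = 1000,
                                      seed = 1L,
                                      scheme = c("label", "value")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  win <- as.character(E_both$samples$window)
  levs <- unique(win)
  stopifnot(length(levs) == 2)
  pre_idx <- which(win == levs[1]); post_idx <- which(win == levs[2])
  m <- E_both$values[as.character(module_genes), , drop = FALSE]
  r1 <- upper_tri_mean(row_cor(m[, pre_idx, drop = FALSE]), na.rm = TRUE)
  r2 <- upper_tri_mean(row_cor(m[, post_idx, drop = FALSE]), na.rm = TRUE)
  obs <- r2 - r1
  set.seed(derive_seed(seed, paste(module_genes[1], length(module_genes))))
  n <- ncol(m)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (scheme == "label") {
      idx <- sample.int(n)
      p1 <- idx[seq_along(pre_idx)]
      p2 <- idx[length(pre_idx) + seq_along(post_idx)]
      mp <- m
    } else {
      mp <- t(apply(m, 1, sample))
      p1 <- pre_idx; p2 <- post_idx
    }
    dp <- upper_tri_mean(row_cor(mp[, p2, drop = FALSE]), na.rm = TRUE) -
          upper_tri_mean(row_cor(mp[, p1, drop = FALSE]), na.rm = TRUE)
    if (abs(dp) >= abs(obs)) exceed <- exceed + 1L
  }
  structure(list(n_genes = length(module_genes), mean_r_pre = r1,
                 mean_r_post = r1 + obs, delta = obs,
                 p = (1 + exceed) / (n_perm + 1), n_perm = n_perm,
                 scheme = scheme),
            class = "ModuleRewiringStat")
}

#' Full differential-coexpression chain
#'
#' Convenience wrapper running coexpression (per window), adjacency
#' difference, TOM, average-linkage clustering of 1 - TOM, adaptive tree
#' cut and eigengene merging, at the standard defaults (beta = 6, minimum
#' module size 100, deep split, merge threshold r = 0.9).
#'
#' @param E pooled [expression_matrix()] with a two-level window.
#' @param beta soft threshold (default 6).
#' @param min_module_size minimum module size (default 100).
#' @param deep_split enable the extra branch-refinement pass (default TRUE).
#' @param merge_r eigengene correlation threshold for merging (default 0.9).
#' @param block_size TOM block size.
#' @return list with `assignment` (named gene -> module id vector, 0 =
#'   unassigned), `eigengenes`, `dendrogram`, `modules_before_merge`,
#'   `scale_free_r2`, `rewiring` (data.frame of per-module statistics,
#'   without permutation p; see [rewiring_permutation_test()]).
#' @export
diffcoex_chain <- function(E, beta = 6, min_module_size = 100,
                           deep_split = TRUE, merge_r = 0.9,
                           block_size = 2000) {
  wins <- split_samples(E, "window")
  levs <- unique(as.character(E$samples$window))
  E_pre <- wins[[levs[1]]]; E_post <- wins[[levs[2]]]
  C_pre <- coexpression(E_pre)
  C_post <- coexpression(E_post)
  D <- adjacency_difference(C_pre, C_post, beta = beta)
  r2 <- tryCatch(scale_free_fit(D), error = function(e) NA_real_)
  TOM <- topological_overlap(D, block_size = block_size)
  dend <- average_linkage_cluster(stats::as.dist(1 - TOM))
  assign0 <- cut_modules(dend, min_module_size = min_module_size,
                         deep_split = deep_split)
  merged <- merge_modules(E, assign0, r_threshold = merge_r)
  rw <- per_module_rewiring(E_pre, E_post, merged$assignment)
  list(assignment = merged$assignment, eigengenes = merged$eigengenes,
       dendrogram = dend, modules_before_merge = assign0,
       scale_free_r2 = r2, rewiring = rw,
       C_pre = C_pre, C_post = C_post)
}

per_module_rewiring <- function(E_pre, E_post, assignment) {
  mods <- sort(setdiff(unique(assignment), 0))
  if (!length(mods))
    return(data.frame(module = integer(0), n_genes = integer(0),
                      mean_r_pre = numeric(0), mean_r_post = numeric(0),
                      delta = numeric(0)))
  rows <- lapply(mods, function(m) {
    g <- names(assignment)[assignment == m]
    st <- rewiring_statistic(E_pre, E_post, g)
    data.frame(module = m, n_genes = st$n_genes, mean_r_pre = st$mean_r_pre,
               mean_r_post = st$mean_r_post, delta = st$delta)
  })
  do.call(rbind, rows)
}
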
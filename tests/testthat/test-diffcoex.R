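stratum_E <- function(values) {
  n <- ncol(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  meta <- data.frame(sample_id = paste0("s", seq_len(n)),
                     region = "R1", age = paste0("a", seq_len(n)),
                     window = rep("prenatal", n))
  colnames(values) <- meta$sample_id
  expression_matrix(values, meta)
}

as_coex <- function(C) structure(C, class = c("CoexpressionMatrix", "matrix"))

test_that("coexpression matches the double-loop Pearson oracle", {
  set.seed(1)
  v <- matrix(rnorm(200), 20, 10)
  C <- coexpression(stratum_E(v))
  expect_lt(max(abs(unclass(C) - naive_row_cor(v)), na.rm = TRUE), 1e-12)
  expect_true(isSymmetric(unclass(C)))
  # identical and negated gene pairs
  v2 <- rbind(a = v[1, ], b = v[1, ], c = -v[1, ])
  C2 <- coexpression(stratum_E(v2))
  expect_equal(C2["a", "b"], 1)
  expect_equal(C2["a", "c"], -1)
  expect_error(coexpression(stratum_E(v[, 1:2])), "3 samples")
  # constant gene flagged
  v3 <- v; v3[5, ] <- 2
  C3 <- coexpression(stratum_E(v3))
  expect_identical(attr(C3, "constant_genes"), "g005")
  expect_true(all(is.na(C3["g005", ])))
})

test_that("adjacency_difference follows the signed-squared formula", {
  g <- c("a", "b")
  mk <- function(r) as_coex(matrix(c(1, r, r, 1), 2, 2,
                                   dimnames = list(g, g)))
  expect_equal(unclass(adjacency_difference(mk(0.5), mk(0.5)))[1, 2], 0)
  expect_equal(unclass(adjacency_difference(mk(1), mk(-1)))[1, 2], 1)
  expect_equal(unclass(adjacency_difference(mk(0.9), mk(0.1)))[1, 2],
               (0.5 * abs(0.81 - 0.01))^3)
  # order of conditions does not change D
  set.seed(2)
  v1 <- matrix(rnorm(80), 8, 10); v2 <- matrix(rnorm(80), 8, 10)
  C1 <- coexpression(stratum_E(v1)); C2 <- coexpression(stratum_E(v2))
  expect_equal(unclass(adjacency_difference(C1, C2)),
               unclass(adjacency_difference(C2, C1)))
  expect_true(all(unclass(adjacency_difference(C1, C2)) >= 0))
  expect_true(all(unclass(adjacency_difference(C1, C2)) <= 1))
  C3 <- C1; rownames(C3)[1] <- colnames(C3)[1] <- "zzz"
  expect_error(adjacency_difference(C1, C3), "mismatched")
})

test_that("scale_free_fit: constructed power law and degenerate cases", {
  n <- 300
  u <- (seq_len(n) - 0.5) / n
  w <- 0.5 * u^(1 / 1.5)      # inverse-CDF draws from a power law
  D <- outer(w, w); diag(D) <- 0
  expect_gt(scale_free_fit(D), 0.95)
  expect_lte(scale_free_fit(D), 1)
  expect_error(scale_free_fit(matrix(0.5, 4, 4) - 0.5 * diag(4)),
               "identical")
})

test_that("beta sweep yields a valid fit index at the default beta = 6", {
  sim <- simulate_expression(default_module_specs(60, 150),
                             n_regions = 4, n_timepoints_per_window = 7,
                             seed = 19)
  wins <- split_samples(sim$expression, "window")
  C1 <- coexpression(wins$prenatal); C2 <- coexpression(wins$postnatal)
  r2 <- vapply(c(2, 4, 6), function(b)
    scale_free_fit(adjacency_difference(C1, C2, beta = b)), numeric(1))
  expect_true(all(is.finite(r2) & r2 >= 0 & r2 <= 1))
})

test_that("topological_overlap: closed forms, oracle, blockwise identity", {
  z <- matrix(0, 5, 5)
  expect_equal(topological_overlap(structure(z, class = "DiffAdjacency")),
               diag(5), ignore_attr = TRUE)
  cg <- matrix(1, 4, 4); diag(cg) <- 0
  T4 <- topological_overlap(structure(cg, class = "DiffAdjacency"))
  expect_equal(unique(T4[upper.tri(T4)]), 1)
  for (s in 1:10) {
    set.seed(s)
    A <- matrix(runif(225, 0, 0.5), 15, 15); A <- (A + t(A)) / 2
    diag(A) <- 0
    got <- topological_overlap(A)
    expect_lt(max(abs(got - naive_tom(A))), 1e-12)
    expect_equal(topological_overlap(A, block_size = 4), got)
    expect_true(all(got >= 0 & got <= 1 + 1e-12))
  }
})

planted_block_adjacency <- function(sizes, within = 0.6, between = 0.005,
                                    seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  D <- matrix(between, n, n) + matrix(runif(n * n, 0, 0.002), n, n)
  D <- (D + t(D)) / 2
  off <- 0
  for (s in sizes) {
    idx <- off + seq_len(s); off <- off + s
    D[idx, idx] <- within + matrix(runif(s * s, 0, 0.05), s, s)
    D[idx, idx] <- (D[idx, idx] + t(D[idx, idx])) / 2
  }
  diag(D) <- 0
  dimnames(D) <- list(sprintf("g%04d", 1:n), sprintf("g%04d", 1:n))
  D
}

test_that("cut_modules recovers planted blocks and enforces the size floor", {
  D <- planted_block_adjacency(c(150, 150, 80))
  dend <- average_linkage_cluster(as.dist(1 - topological_overlap(D)))
  a <- cut_modules(dend, min_module_size = 100)
  # each planted block maps to exactly one module; the two differ
  expect_length(unique(a[1:150]), 1L)
  expect_length(unique(a[151:300]), 1L)
  expect_false(a[1] == a[151])
  expect_true(all(a[1:300] != 0))
  expect_setequal(unique(a), c(0L, 1L, 2L))   # the 80-block is under size
  # blocks below the floor: zero modules, with a warning
  Dh <- planted_block_adjacency(c(80, 80))
  dh <- average_linkage_cluster(as.dist(1 - topological_overlap(Dh)))
  expect_warning(ah <- cut_modules(dh, min_module_size = 100), "no modules")
  expect_true(all(ah == 0))
  expect_warning(a0 <- cut_modules(dend, min_module_size = 1000),
                 "exceeds gene count")
  expect_true(all(a0 == 0))
})

test_that("module_eigengenes: degenerate modules and factor recovery", {
  sim <- simulate_expression(list(module_spec(80, "stable", noise_sd = 0.3),
                                  module_spec(40, "background")),
                             region_effect_sd = 0, seed = 23)
  tr <- sim$truth$genes
  assign <- setNames(ifelse(tr$type == "stable", 1L, 0L), tr$gene)
  eig <- module_eigengenes(sim$expression, assign)
  expect_gt(abs(cor(eig$eigengenes[, "1"], sim$truth$factors[, "stable"])),
            0.95)
  # module of identical genes: eigengene is the shared standardized profile
  E <- sim$expression
  v <- rbind(a = E$values[1, ], b = E$values[1, ], c = E$values[1, ])
  colnames(v) <- E$samples$sample_id
  Eid <- expression_matrix(v, E$samples)
  ei <- module_eigengenes(Eid, setNames(c(1L, 1L, 1L), c("a", "b", "c")))
  prof <- as.numeric(scale(E$values[1, ]))
  expect_equal(abs(cor(ei$eigengenes[, 1], prof)), 1)
  expect_equal(ei$variance_explained[[1]], 1)
  # duplicating a member gene leaves the eigengene invariant up to sign
  g <- tr$gene[tr$type == "stable"]
  vdup <- rbind(E$values[g, ], dup = E$values[g[1], ])
  Edup <- expression_matrix(vdup, E$samples)
  adup <- setNames(rep(1L, length(g) + 1), rownames(vdup))
  edup <- module_eigengenes(Edup, adup)
  expect_gt(abs(cor(edup$eigengenes[, 1],
                    module_eigengenes(sim$expression, assign)$eigengenes[, 1])),
            0.999)
  expect_error(module_eigengenes(E, setNames(c(1L, rep(0L, nrow(E$values) - 1)),
                                             gene_ids(E))), "fewer than 2")
})

test_that("merge_modules joins duplicate-factor modules and spares orthogonal ones", {
  # 6 planted modules where two pairs share a factor: 6 -> 4 after merging
  specs <- lapply(1:4, function(i) module_spec(40, "stable",
                                               module_id = paste0("m", i)))
  sim <- simulate_expression(specs, region_effect_sd = 0, seed = 29)
  E <- sim$expression
  tr <- sim$truth$genes
  # duplicate factors: split m1 and m2 in two halves each -> 6 labels
  lab <- tr$module
  for (m in c("m1", "m2")) {
    idx <- which(lab == m)
    lab[idx[seq_len(20)]] <- paste0(m, "_a")
    lab[idx[21:40]] <- paste0(m, "_b")
  }
  assign <- setNames(as.integer(factor(lab)), tr$gene)
  res <- merge_modules(E, assign, r_threshold = 0.9)
  expect_identical(length(setdiff(unique(res$assignment), 0L)), 4L)
  expect_gte(res$n_merges, 2L)
  # orthogonal factors stay separate
  assign2 <- setNames(as.integer(factor(tr$module)), tr$gene)
  res2 <- merge_modules(E, assign2, r_threshold = 0.9)
  expect_identical(res2$n_merges, 0L)
})

test_that("rewiring statistic sign tracks the planted direction", {
  sim <- simulate_expression(list(module_spec(100, "gain"),
                                  module_spec(100, "loss"),
                                  module_spec(100, "background")),
                             seed = 37)
  wins <- split_samples(sim$expression, "window")
  tr <- sim$truth$genes
  g_gain <- tr$gene[tr$type == "gain"]; g_loss <- tr$gene[tr$type == "loss"]
  st_gain <- rewiring_statistic(wins$prenatal, wins$postnatal, g_gain)
  st_loss <- rewiring_statistic(wins$prenatal, wins$postnatal, g_loss)
  expect_gt(st_gain$delta, 0.5)
  expect_lt(st_loss$delta, -0.5)
  # identical strata give delta exactly 0
  st0 <- rewiring_statistic(wins$prenatal, wins$prenatal, g_gain)
  expect_equal(st0$delta, 0)
})

test_that("rewiring permutation test hits the resolution floor and is reproducible", {
  sim <- simulate_expression(list(module_spec(60, "gain"),
                                  module_spec(60, "background")),
                             seed = 43)
  g <- sim$truth$genes$gene[sim$truth$genes$type == "gain"]
  pt <- rewiring_permutation_test(sim$expression, g, n_perm = 200, seed = 3)
  expect_equal(pt$p, 1 / 201)
  pt2 <- rewiring_permutation_test(sim$expression, g, n_perm = 200, seed = 3)
  expect_identical(pt$p, pt2$p)
  expect_error(rewiring_permutation_test(sim$expression, g, n_perm = 0),
               "n_perm")
  # value-shuffle scheme also flags a planted module
  pv <- rewiring_permutation_test(sim$expression, g, n_perm = 99, seed = 3,
                                  scheme = "value")
  expect_lte(pv$p, 0.05)
})
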
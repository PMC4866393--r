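# Module-wise functional enrichment: Z-score test with resampling nulls,
# hypergeometric alternative, TF-motif exclusivity permutation test,
# overlap counts, two-group differential expression, and targeted term
# queries.

#' Z-score gene-set enrichment with a resampling null
#'
#' For each retained term, the observed overlap with the module is compared
#' with the mean and sd of the overlap across `n_samples` equally-sized
#' random gene sets drawn (without replacement by default) from the
#' background population. p values are two-sided normal, BH-adjusted across
#' terms within the module, and a term is flagged significant only when
#' `fdr < alpha` AND the over-representation rule `observed - expected > 1`
#' holds; under-representation is reported but never flagged.
#'
#' @param module_genes character vector of gene ids (subset of background).
#' @param terms a [gene_set_collection()].
#' @param n_samples number of random draws (default 10000).
#' @param alpha FDR threshold (default 0.05).
#' @param seed integer seed.
#' @param replace sample the null with replacement (default FALSE).
#' @param term_ids optional explicit term subset (used by
#'   [targeted_term_query()]); defaults to the retained (size-filtered)
#'   terms.
#' @return data.frame of class `EnrichmentTable` with columns `term`,
#'   `term_size`, `observed`, `expected`, `expected_sd`, `z`, `p`, `fdr`,
#'   `significant`, `degenerate`.
#' @export
zscore_enrichment <- function(module_genes, terms, n_samples = 10000,
                              alpha = 0.05, seed = 1L, replace = FALSE,
                              term_ids = NULL) {
  stopifnot(inherits(terms, "GeneSetCollection"))
  bg <- terms$background
  module_genes <- intersect(as.character(module_genes), bg)
  if (!length(module_genes)) stop("module has no genes in the background")
  ids <- term_ids %||% terms$retained
  if (!length(ids)) stop("no terms to test")
  m <- length(module_genes)
  nbg <- length(bg)
  idx <- setNames(seq_len(nbg), bg)
  term_idx <- lapply(terms$sets[ids], function(g) unname(idx[g]))
  obs <- vapply(terms$sets[ids],
                function(g) length(intersect(g, module_genes)), integer(1))
  set.seed(derive_seed(seed, paste0("zscore", m)))
  counts <- matrix(0L, n_samples, length(ids))
  member <- logical(nbg)
  for (b in seq_len(n_samples)) {
    draw <- sample.int(nbg, m, replace = replace)
    member[draw] <- TRUE
    counts[b, ] <- vapply(term_idx, function(ti) sum(member[ti]), integer(1))
    member[draw] <- FALSE
  }
  mu <- colMeans(counts)
  sdv <- apply(counts, 2, stats::sd)
  degenerate <- sdv == 0
  z <- ifelse(degenerate, NA_real_, (obs - mu) / sdv)
  p <- ifelse(degenerate, NA_real_, 2 * stats::pnorm(-abs(z)))
  fdr <- bh_adjust(p)
  out <- data.frame(term = ids,
                    term_size = lengths(terms$sets[ids]),
                    observed = obs, expected = mu, expected_sd = sdv,
                    z = z, p = p, fdr = fdr,
                    significant = !is.na(fdr) & fdr < alpha & (obs - mu) > 1,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the module/term overlap against the
#' background universe, BH-adjusted; the closed-form alternative to
#' [zscore_enrichment()].
#'
#' @inheritParams zscore_enrichment
#' @return data.frame of class `EnrichmentTable` with columns `term`,
#'   `term_size`, `observed`, `expected`, `p`, `fdr`, `significant`.
#' @export
hypergeom_enrichment <- function(module_genes, terms, alpha = 0.05,
                                 term_ids = NULL) {
  stopifnot(inherits(terms, "GeneSetCollection"))
  bg <- terms$background
  module_genes <- intersect(as.character(module_genes), bg)
  if (!length(module_genes)) stop("module has no genes in the background")
  ids <- term_ids %||% terms$retained
  if (!length(ids)) stop("no terms to test")
  nbg <- length(bg)
  K <- lengths(terms$sets[ids])
  if (any(K > nbg)) stop("term larger than background")
  m <- length(module_genes)
  obs <- vapply(terms$sets[ids],
                function(g) length(intersect(g, module_genes)), integer(1))
  p <- stats::phyper(obs - 1, K, nbg - K, m, lower.tail = FALSE)
  expected <- m * K / nbg
  fdr <- bh_adjust(p)
  out <- data.frame(term = ids, term_size = unname(K), observed = obs,
                    expected = unname(expected), p = unname(p), fdr = fdr,
                    significant = fdr < alpha & (obs - expected) > 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Permutation test of motif exclusivity across modules
#'
#' Tests whether the number of motifs enriched in exactly one module
#' exceeds chance. The default null preserves each module's enriched-set
#' size and resamples members uniformly without replacement from the motif
#' universe; an alternative marginal-preserving null (`"swap"`) randomizes
#' the module x motif incidence matrix by checkerboard swaps, preserving
#' both module sizes and per-motif frequencies.
#'
#' @param enriched named list: module id -> character vector of enriched
#'   motif ids.
#' @param motif_universe candidate motif pool; defaults to the union of all
#'   enriched motifs.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param null `"size"` (default) or `"swap"`.
#' @return list of class `ExclusivityResult`: `observed`, `perm_mean`,
#'   `perm_sd`, `p`, `n_perm`, `null`.
#' @export
tf_exclusivity_test <- function(enriched, motif_universe = NULL,
                                n_perm = 10000, seed = 1L,
                                null = c("size", "swap")) {
  null <- match.arg(null)
  enriched <- lapply(enriched, as.character)
  motif_universe <- unique(motif_universe %||% unlist(enriched))
  if (!length(motif_universe)) stop("empty motif universe")
  if (!all(unlist(enriched) %in% motif_universe))
    stop("enriched motifs outside the declared universe")
  count_exclusive <- function(sets) {
    tab <- table(unlist(lapply(sets, unique)))
    sum(tab == 1L)
  }
  obs <- count_exclusive(enriched)
  sizes <- lengths(enriched)
  set.seed(derive_seed(seed, paste0("excl", length(enriched))))
  stat <- numeric(n_perm)
  if (null == "size") {
    for (b in seq_len(n_perm))
      stat[b] <- count_exclusive(lapply(sizes, function(s)
        sample(motif_universe, s)))
  } else {
    inc <- do.call(rbind, lapply(enriched, function(s)
      motif_universe %in% s))
    for (b in seq_len(n_perm)) {
      inc_b <- curveball_shuffle(inc, n_swaps = 5L * nrow(inc))
      stat[b] <- sum(colSums(inc_b) == 1L & colSums(inc_b) > 0L)
    }
  }
  structure(list(observed = obs, perm_mean = mean(stat),
                 perm_sd = stats::sd(stat),
                 p = (1 + sum(stat >= obs)) / (n_perm + 1),
                 n_perm = n_perm, null = null),
            class = "ExclusivityResult")
}

# Curveball-style margin-preserving randomization of a binary incidence
# matrix: repeatedly pick two rows and trade motifs unique to each.
curveball_shuffle <- function(inc, n_swaps) {
  nr <- nrow(inc)
  if (nr < 2) return(inc)
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(nr, 2)
    a <- inc[ij[1], ]; b <- inc[ij[2], ]
    only_a <- which(a & !b); only_b <- which(b & !a)
    k <- min(length(only_a), length(only_b))
    if (k == 0) next
    n_trade <- sample.int(k, 1)
    ta <- if (length(only_a) == 1) only_a else sample(only_a, n_trade)
    tb <- if (length(only_b) == 1) only_b else sample(only_b, n_trade)
    a[ta] <- FALSE; a[tb] <- TRUE
    b[tb] <- FALSE; b[ta] <- TRUE
    inc[ij[1], ] <- a; inc[ij[2], ] <- b
  }
  inc
}

#' Pairwise overlap counts and exclusive counts of enriched motif sets
#'
#' @param enriched named list: module id -> motif set.
#' @return list with `overlap` (symmetric count matrix, diagonal = set
#'   sizes), `exclusive` (per-module count of motifs enriched only there)
#'   and `n_exclusive_total` (consistent with the observed statistic of
#'   [tf_exclusivity_test()]).
#' @export
overlap_counts <- function(enriched) {
  enriched <- lapply(enriched, unique)
  mods <- names(enriched) %||% paste0("M", seq_along(enriched))
  k <- length(enriched)
  ov <- matrix(0L, k, k, dimnames = list(mods, mods))
  for (i in seq_len(k)) for (j in seq_len(k))
    ov[i, j] <- length(intersect(enriched[[i]], enriched[[j]]))
  tab <- table(unlist(enriched))
  excl <- vapply(enriched, function(s) sum(tab[s] == 1L), integer(1))
  names(excl) <- mods
  list(overlap = ov, exclusive = excl,
       n_exclusive_total = sum(tab == 1L))
}

#' Two-group differential expression (Welch t test + BH)
#'
#' Per-gene Welch t statistic between the two condition windows with BH
#' false-discovery-rate control; a deliberately plain replacement for
#' moderated-variance methods. Genes with zero variance in both groups are
#' flagged and excluded from testing.
#'
#' @param E pooled [expression_matrix()] with both windows (>= 3 samples
#'   each), or pass `E_post` to supply the two strata separately.
#' @param E_post optional second-stratum [expression_matrix()].
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with columns `gene`, `mean_pre`, `mean_post`, `t`,
#'   `df`, `p`, `fdr`, `de`, `flagged`.
#' @export
differential_expression <- function(E, E_post = NULL, alpha = 0.05) {
  if (is.null(E_post)) {
    wins <- split_samples(E, "window")
    levs <- unique(as.character(E$samples$window))
    x <- wins[[levs[1]]]$values; y <- wins[[levs[2]]]$values
  } else {
    x <- E$values; y <- E_post$values
  }
  if (ncol(x) < 3 || ncol(y) < 3) stop("need >= 3 samples per window")
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- matrixStats_rowVars(x); v2 <- matrixStats_rowVars(y)
  flagged <- v1 == 0 & v2 == 0
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(flagged, NA_real_, (m2 - m1) / sqrt(se2))
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  fdr <- bh_adjust(p)
  data.frame(gene = rownames(x), mean_pre = m1, mean_post = m2,
             t = tstat, df = df, p = p, fdr = fdr,
             de = !is.na(fdr) & fdr < alpha, flagged = flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Targeted enrichment query of an explicit term list
#'
#' Same statistics as [zscore_enrichment()], restricted (including the BH
#' family) to the queried term ids; ids absent from the collection are
#' reported, not fatal. The term-size filter is bypassed: a targeted query
#' may legitimately name small terms.
#'
#' @param genes gene set of interest (e.g. DE genes).
#' @param terms a [gene_set_collection()].
#' @param term_ids explicit term ids to test (>= 1).
#' @param ... passed to [zscore_enrichment()] (`n_samples`, `alpha`,
#'   `seed`).
#' @return list with `table` (an `EnrichmentTable` over the present ids)
#'   and `missing` (ids not found in the collection).
#' @export
targeted_term_query <- function(genes, terms, term_ids, ...) {
  if (!length(term_ids)) stop("empty query list")
  term_ids <- as.character(term_ids)
  present <- intersect(term_ids, names(terms$sets))
  missing <- setdiff(term_ids, present)
  if (!length(present))
    return(list(table = NULL, missing = missing))
  tab <- zscore_enrichment(genes, terms, term_ids = present, ...)
  list(table = tab, missing = missing)
}
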
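# Global transcriptome comparison: PCA with factor association,
# average-profile clustering across region x window strata, and clustering
# of whole coexpression structures under the 1 - R distance.

#' Principal component scores of samples
#'
#' Samples are observations, genes are variables; genes are centred and
#' optionally scaled to unit variance. Component signs are fixed by making
#' the largest-magnitude gene loading positive, so results are fully
#' deterministic.
#'
#' @param E an [expression_matrix()].
#' @param scale. scale genes to unit variance (default FALSE: variance
#'   shares refer to the raw profile spread).
#' @return list of class `PCAResult`: `scores` (samples x components),
#'   `variance_fraction`, `loadings`.
#' @export
pca_scores <- function(E, scale. = FALSE) {
  if (ncol(E$values) < 2) stop("PCA needs at least 2 samples")
  x <- t(E$values)
  if (scale.) {
    v <- matrixStats_rowVars(E$values)
    x <- x[, v > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    r <- p$rotation[, j]
    sign(r[which.max(abs(r))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  rot <- sweep(p$rotation, 2, flip, `*`)
  structure(list(scores = scores,
                 variance_fraction = p$sdev^2 / sum(p$sdev^2),
                 loadings = rot),
            class = "PCAResult")
}

#' Kruskal-Wallis association between a score and a grouping
#'
#' Rank-based test of whether a per-sample quantity (typically PC1) differs
#' between groups, with the usual tie correction. All-tied input returns
#' H = 0 with a warning rather than dividing by zero.
#'
#' @param scores numeric per-sample values.
#' @param grouping per-sample labels (>= 2 nonempty groups).
#' @return list with `H` (tie-corrected statistic), `df`, `p`.
#' @export
factor_association <- function(scores, grouping) {
  grouping <- as.factor(as.character(grouping))
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  if (any(table(grouping) == 0)) stop("empty group in grouping")
  if (length(unique(scores)) == 1L) {
    warning("all scores identical; H set to 0")
    return(list(H = 0, df = nlevels(grouping) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(scores, grouping)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Average expression profiles per (region, window) stratum
#'
#' @param E an [expression_matrix()].
#' @return genes x strata matrix of per-stratum mean expression; column
#'   names are `region.window`.
#' @export
average_profiles <- function(E) {
  groups <- split_samples(E, "region_window")
  if (any(vapply(groups, function(g) ncol(g$values), integer(1)) == 0))
    stop("empty stratum")
  out <- vapply(groups, function(g) rowMeans(g$values),
                numeric(nrow(E$values)))
  out
}

#' Correlation distance (1 - Pearson R) between profiles or matrices
#'
#' For a list of symmetric coexpression matrices the comparison uses the
#' strictly-upper-triangle entries only (the unit diagonal carries no
#' information and would inflate R); for a plain matrix each column is a
#' profile. `NA` entries (e.g. correlations of within-stratum-constant
#' genes) are dropped pairwise.
#'
#' @param x either a numeric matrix whose columns are profiles, or a list of
#'   equal-dimension numeric matrices.
#' @return object of class `DistanceMatrix`: symmetric matrix of 1 - R with
#'   zero diagonal, entries in \[0, 2\].
#' @export
correlation_distance_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    dims <- unique(lapply(x, dim))
    if (length(dims) != 1) stop("matrices must share dimensions")
    labs <- names(x) %||% paste0("M", seq_along(x))
    cols <- vapply(x, function(m) {
      if (nrow(m) == ncol(m)) m[upper.tri(m)] else as.vector(m)
    }, numeric(if (nrow(x[[1]]) == ncol(x[[1]]))
                 sum(upper.tri(x[[1]])) else length(x[[1]])))
    colnames(cols) <- labs
    x <- cols
  }
  if (ncol(x) < 2) stop("need at least 2 profiles")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds)) || any(sds == 0))
    stop("constant input array (undefined correlation): ",
         paste(colnames(x)[is.na(sds) | sds == 0], collapse = ", "))
  R <- stats::cor(x, use = "pairwise.complete.obs")
  d <- 1 - R
  diag(d) <- 0
  structure(d, class = c("DistanceMatrix", "matrix"))
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' @param D a symmetric distance matrix (e.g. from
#'   [correlation_distance_matrix()]) or a `dist` object.
#' @return an [stats::hclust] dendrogram (agglomeration `"average"`).
#' @export
average_linkage_cluster <- function(D) {
  d <- if (inherits(D, "dist")) D else stats::as.dist(unclass(D))
  if (attr(d, "Size") < 2) stop("need at least 2 leaves")
  stats::hclust(d, method = "average")
}

#' Two leaf sets of the final dendrogram merge
#'
#' Formalizes "does the dendrogram split condition A from condition B" as a
#' testable partition: the two subtrees joined by the last merge.
#'
#' @param dend an [stats::hclust] object.
#' @return list of two character vectors of leaf labels.
#' @export
top_split <- function(dend) {
  stopifnot(inherits(dend, "hclust"))
  k <- stats::cutree(dend, k = 2)
  labs <- names(k) %||% as.character(seq_along(k))
  list(A = labs[k == 1], B = labs[k == 2])
}

# TRUE if a 2-set partition equals a reference 2-set partition.
same_partition <- function(split, ref_a, ref_b) {
  (setequal(split$A, ref_a) && setequal(split$B, ref_b)) ||
    (setequal(split$A, ref_b) && setequal(split$B, ref_a))
}

#' Per-stratum coexpression matrices
#'
#' Convenience wrapper computing one coexpression matrix per
#' (region, window) stratum, the substrate of the coexpression-structure
#' dendrogram.
#'
#' @param E an [expression_matrix()].
#' @return named list of `CoexpressionMatrix` objects.
#' @export
stratum_coexpression <- function(E) {
  lapply(split_samples(E, "region_window"), coexpression)
}
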
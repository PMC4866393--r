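# Module eigengenes (first principal component of the standardized module
# expression) and eigengene-correlation module merging.

#' Module eigengenes
#'
#' For each module, genes are standardized across the pooled samples and the
#' first right singular vector gives the per-sample eigengene; its sign is
#' oriented to correlate positively with the module's mean standardized
#' profile. Eigengenes are computed on the pooled (both-window) samples: a
#' module must behave as one unit across the whole design to be mergeable.
#'
#' @param E pooled [expression_matrix()] containing all assigned genes.
#' @param assignment named gene -> module id vector (0 = unassigned), as
#'   returned by [cut_modules()].
#' @return list of class `EigengeneSet`: `eigengenes` (samples x modules
#'   matrix), `variance_explained` (per module).
#' @export
module_eigengenes <- function(E, assignment) {
  mods <- sort(setdiff(unique(assignment), 0))
  if (!length(mods)) stop("no modules to compute eigengenes for")
  eg <- matrix(NA_real_, ncol(E$values), length(mods),
               dimnames = list(colnames(E$values), as.character(mods)))
  ve <- setNames(numeric(length(mods)), as.character(mods))
  for (j in seq_along(mods)) {
    g <- names(assignment)[assignment == mods[j]]
    if (length(g) < 2) stop("module ", mods[j], " has fewer than 2 genes")
    x <- E$values[g, , drop = FALSE]
    x <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
    x <- x[is.finite(rowSums(x)), , drop = FALSE]   # drop constant genes
    sv <- svd(x, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(x)) < 0) e <- -e
    eg[, j] <- e
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = eg, variance_explained = ve),
            class = "EigengeneSet")
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the most-correlated module pair whose eigengene
#' correlation exceeds `r_threshold`, recomputing eigengenes after every
#' merge, until no pair exceeds the threshold. Module ids are then relabeled
#' 1..K by decreasing size.
#'
#' @param E pooled [expression_matrix()].
#' @param assignment named gene -> module id vector (0 = unassigned).
#' @param r_threshold eigengene correlation above which modules merge
#'   (default 0.9).
#' @return list with `assignment` (relabeled), `eigengenes`
#'   (an `EigengeneSet` for the final modules), `n_merges`.
#' @export
merge_modules <- function(E, assignment, r_threshold = 0.9) {
  assignment <- assignment  # copy
  n_merges <- 0L
  repeat {
    mods <- sort(setdiff(unique(assignment), 0))
    if (length(mods) < 2) break
    eig <- module_eigengenes(E, assignment)
    R <- stats::cor(eig$eigengenes)
    diag(R) <- -Inf
    best <- which(R == max(R), arr.ind = TRUE)[1, ]
    if (R[best[1], best[2]] <= r_threshold) break
    a <- as.integer(colnames(R)[best[1]])
    b <- as.integer(colnames(R)[best[2]])
    assignment[assignment == max(a, b)] <- min(a, b)
    n_merges <- n_merges + 1L
  }
  mods <- setdiff(unique(assignment), 0)
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(assignment == m), integer(1))
    relab <- setNames(seq_along(mods), mods[order(-sizes)])
    old <- assignment
    for (m in names(relab)) assignment[old == as.integer(m)] <- relab[[m]]
    eig <- module_eigengenes(E, assignment)
  } else {
    eig <- NULL
  }
  list(assignment = assignment, eigengenes = eig, n_merges = n_merges)
}
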
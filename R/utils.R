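# Internal numeric helpers shared across the pipeline.

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false discovery rate control. Implemented directly (rather than
#' delegating to [stats::p.adjust()]) so that the multiple-testing rule used
#' by the enrichment tables is an auditable part of this package; the test
#' suite checks equivalence against the reference implementation.
#'
#' @param p numeric vector of p values in \[0, 1\]; `NA`s propagate.
#' @return vector of adjusted p values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  po <- p[ok]
  o <- order(po, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * po[o]))[ro]
  out[ok] <- adj
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects.
#' Label `0` (conventionally "unassigned") is treated as an ordinary cluster,
#' so two labelings that leave the same genes unassigned agree on them.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return scalar ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Mean of the strictly-upper-triangle entries of a square matrix.
upper_tri_mean <- function(m, na.rm = FALSE) {
  mean(m[upper.tri(m)], na.rm = na.rm)
}

# Derive a 32-bit sub-seed from a top-level seed and a stream label, so that
# per-module permutation streams are reproducible and non-overlapping.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
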
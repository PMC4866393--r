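# Gene-set collections in GMT format (term <TAB> description <TAB> genes...).

#' Build a gene-set collection against a background universe
#'
#' Member lists are intersected with the background; terms whose
#' post-intersection size falls below `min_term_size` are kept in the
#' collection but flagged as excluded, and are skipped by the module-wise
#' enrichment scans (targeted queries may still use them).
#'
#' @param sets named list: term id -> character vector of member gene ids.
#' @param background character vector, the gene universe.
#' @param names optional named character vector of term descriptions.
#' @param min_term_size minimum post-intersection size for a term to take
#'   part in untargeted enrichment scans (default 150).
#' @return object of class `GeneSetCollection` with elements `sets`
#'   (intersected members), `names`, `background`, `retained` and `excluded`
#'   (term id vectors) and `min_term_size`.
#' @export
gene_set_collection <- function(sets, background, names = NULL,
                                min_term_size = 150) {
  stopifnot(is.list(sets), length(background) > 0)
  if (length(sets) &&
      (is.null(base::names(sets)) || anyDuplicated(base::names(sets))))
    stop("term ids must be unique and non-empty")
  background <- unique(as.character(background))
  sets <- lapply(sets, function(g) intersect(as.character(g), background))
  sizes <- vapply(sets, length, integer(1))
  structure(list(sets = sets,
                 names = names,
                 background = background,
                 retained = base::names(sets)[sizes >= min_term_size],
                 excluded = base::names(sets)[sizes < min_term_size],
                 min_term_size = min_term_size),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x$sets), "terms (",
      length(x$retained), "retained >=", x$min_term_size, "genes ) over",
      length(x$background), "background genes\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @param background gene universe to intersect against.
#' @param min_term_size see [gene_set_collection()].
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, background, min_term_size = 150) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (need term, description, >=1 gene): ",
         paste(bad, collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  descs <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  names(descs) <- ids
  gene_set_collection(sets, background, names = descs,
                      min_term_size = min_term_size)
}

#' Write gene sets to a GMT file
#'
#' @param gsc a [gene_set_collection()] (or plain named list of gene vectors).
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  sets <- if (inherits(gsc, "GeneSetCollection")) gsc$sets else gsc
  descs <- if (inherits(gsc, "GeneSetCollection") && !is.null(gsc$names))
    gsc$names[names(sets)] else setNames(names(sets), names(sets))
  descs[is.na(descs)] <- names(sets)[is.na(descs)]
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descs[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
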
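# Condition-specific high-correlation edges within a module and their
# export as graphs.

#' Classify gene-pair edges by the condition of their high correlation
#'
#' A pair enters the edge set when its correlation exceeds `threshold` in
#' either condition; the class records where: `prenatal_only`,
#' `postnatal_only` or `constant` (both). The test uses the signed
#' correlation r > threshold by default; set `absolute = TRUE` to threshold
#' |r| instead.
#'
#' @param C_pre,C_post `CoexpressionMatrix` objects sharing the module's
#'   genes.
#' @param module_genes character vector of gene ids.
#' @param threshold correlation threshold in (0, 1), default 0.95.
#' @param absolute threshold |r| rather than r (default FALSE).
#' @return data.frame of class `EdgeSet` with columns `gene_a`, `gene_b`
#'   (canonical order `gene_a < gene_b`), `class`; attributes `threshold`,
#'   `genes`.
#' @export
classify_edges <- function(C_pre, C_post, module_genes, threshold = 0.95,
                           absolute = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  module_genes <- as.character(module_genes)
  if (!all(module_genes %in% rownames(C_pre)) ||
      !all(module_genes %in% rownames(C_post)))
    stop("module genes missing from a coexpression matrix")
  a <- unclass(C_pre)[module_genes, module_genes, drop = FALSE]
  b <- unclass(C_post)[module_genes, module_genes, drop = FALSE]
  if (absolute) { a <- abs(a); b <- abs(b) }
  ut <- upper.tri(a)
  hi_pre <- !is.na(a) & a > threshold & ut
  hi_post <- !is.na(b) & b > threshold & ut
  any_hi <- hi_pre | hi_post
  idx <- which(any_hi, arr.ind = TRUE)
  cls <- ifelse(hi_pre[any_hi] & hi_post[any_hi], "constant",
                ifelse(hi_pre[any_hi], "prenatal_only", "postnatal_only"))
  ga <- module_genes[idx[, 1]]; gb <- module_genes[idx[, 2]]
  swap <- ga > gb
  edges <- data.frame(gene_a = ifelse(swap, gb, ga),
                      gene_b = ifelse(swap, ga, gb),
                      class = cls, stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, threshold = threshold, genes = module_genes,
            class = c("EdgeSet", "data.frame"))
}

#' Per-gene and mean degree by condition
#'
#' The prenatal degree of a gene counts its `prenatal_only` plus `constant`
#' edges; likewise postnatal. Means are over all module genes (including
#' isolated ones).
#'
#' @param edges an [classify_edges()] result.
#' @return list with `per_gene` (data.frame gene/degree_pre/degree_post)
#'   and `mean_degree_pre`, `mean_degree_post`.
#' @export
degree_summary <- function(edges) {
  genes <- attr(edges, "genes")
  deg_pre <- deg_post <- setNames(numeric(length(genes)), genes)
  if (nrow(edges)) {
    pre_e <- edges$class %in% c("prenatal_only", "constant")
    post_e <- edges$class %in% c("postnatal_only", "constant")
    for (col in c("gene_a", "gene_b")) {
      tp <- table(edges[[col]][pre_e])
      deg_pre[names(tp)] <- deg_pre[names(tp)] + as.numeric(tp)
      tq <- table(edges[[col]][post_e])
      deg_post[names(tq)] <- deg_post[names(tq)] + as.numeric(tq)
    }
  }
  list(per_gene = data.frame(gene = genes, degree_pre = unname(deg_pre),
                             degree_post = unname(deg_post),
                             stringsAsFactors = FALSE),
       mean_degree_pre = mean(deg_pre),
       mean_degree_post = mean(deg_post))
}

#' Export a classified edge set as GraphML or TSV
#'
#' Nodes are the module genes (isolated genes included); the edge attribute
#' `class` records the condition of the high correlation.
#'
#' @param edges an [classify_edges()] result.
#' @param path output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @return the path, invisibly.
#' @export
export_graph <- function(edges, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(edges), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(as.data.frame(edges),
                                       directed = FALSE,
                                       vertices = attr(edges, "genes"))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
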
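# End-to-end pipeline orchestration with a JSON config and run manifest.

#' Build a run configuration
#'
#' Defaults are the standard analysis parameters: soft threshold beta = 6,
#' minimum module size 100, eigengene merge threshold r = 0.9, edge
#' threshold R > 0.95, 1000 module-rewiring permutations, 10000 enrichment
#' null samples, 10000 exclusivity permutations, alpha = 0.05.
#'
#' @param expression,metadata,gmt input file paths (`expression`/`metadata`
#'   may be omitted when `simulate = TRUE`).
#' @param out_dir output directory.
#' @param simulate generate a synthetic dataset into `out_dir` first.
#' @param beta,min_module_size,deep_split,merge_r,edge_threshold,
#'   n_perm_module,n_samples_enrichment,n_perm_exclusivity,alpha,seed
#'   analysis parameters.
#' @param min_term_size term-size floor for untargeted enrichment.
#' @return a `RunConfig` list.
#' @export
coex_config <- function(expression = NULL, metadata = NULL, gmt = NULL,
                        out_dir = "coexshift_out", simulate = FALSE,
                        beta = 6, min_module_size = 100, deep_split = TRUE,
                        merge_r = 0.9, edge_threshold = 0.95,
                        n_perm_module = 1000, n_samples_enrichment = 10000,
                        n_perm_exclusivity = 10000, alpha = 0.05,
                        min_term_size = 150, seed = 1L) {
  structure(list(expression = expression, metadata = metadata, gmt = gmt,
                 out_dir = out_dir, simulate = simulate, beta = beta,
                 min_module_size = min_module_size, deep_split = deep_split,
                 merge_r = merge_r, edge_threshold = edge_threshold,
                 n_perm_module = n_perm_module,
                 n_samples_enrichment = n_samples_enrichment,
                 n_perm_exclusivity = n_perm_exclusivity, alpha = alpha,
                 min_term_size = min_term_size, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from a JSON file
#'
#' Any field of [coex_config()] may appear in the file; absent fields take
#' their defaults and `overrides` (e.g. from CLI flags) win over the file.
#'
#' @param path JSON file path.
#' @param overrides named list of overriding values.
#' @return a `RunConfig`.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- if (is.null(path)) list() else
    jsonlite::read_json(path, simplifyVector = TRUE)
  vals[names(overrides)] <- overrides
  known <- names(formals(coex_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(coex_config, vals)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) simulate -> expression profile clustering ->
#' coexpression-structure clustering -> differential coexpression (modules,
#' eigengenes, rewiring permutation tests) -> enrichment (if a GMT is
#' supplied) -> per-module edge extraction. Each stage writes its TSV/JSON
#' artifacts under `config$out_dir`; a `manifest.json` records parameters,
#' seed and per-file md5 checksums, so identical configs yield identical
#' manifests. On stage failure a `FAILED` marker naming the stage is left
#' in the output directory and the error is rethrown.
#'
#' @param config a [coex_config()].
#' @param stages subset of stages to run (default all).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "profiles", "structure",
                                    "diffcoex", "enrich", "rewire")) {
  stopifnot(inherits(config, "RunConfig"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- "init"
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (config$simulate && "simulate" %in% stages) {
      stage <- "simulate"
      sim <- simulate_expression(default_module_specs(),
                                 window_shift_sd = 0.5,
                                 seed = config$seed)
      ann <- simulate_annotations(sim$truth, n_terms = 40,
                                  seed = config$seed)
      files <- c(files, write_simulation(sim, out, annotations = ann))
      config$expression <- file.path(out, "expression.tsv")
      config$metadata <- file.path(out, "metadata.tsv")
      config$gmt <- config$gmt %||% file.path(out, "annotations.gmt")
    }
    stage <- "read"
    for (p in c(config$expression, config$metadata))
      if (!file.exists(p)) stop("input not found: ", p)
    E <- read_expression(config$expression, config$metadata)
    E <- filter_zero_variance(E)
    message("expression: ", nrow(E$values), " genes x ", ncol(E$values),
            " samples after variance filter")
    wins <- split_samples(E, "window")
    levs <- unique(as.character(E$samples$window))

    if ("profiles" %in% stages) {
      stage <- "profiles"
      pca <- pca_scores(E)
      kw_win <- factor_association(pca$scores[, 1], E$samples$window)
      kw_reg <- factor_association(pca$scores[, 1], E$samples$region)
      prof <- average_profiles(E)
      Dp <- correlation_distance_matrix(prof)
      dend <- average_linkage_cluster(Dp)
      sp <- top_split(dend)
      files <- c(files,
                 write_tsv(as.data.frame(unclass(Dp)),
                           file.path(out, "profile_distance.tsv")))
      jsonlite::write_json(
        list(pc_variance_fraction = pca$variance_fraction,
             pc12_variance_pct = 100 * sum(pca$variance_fraction[1:2]),
             kruskal_wallis = list(window = kw_win, region = kw_reg),
             top_split = sp),
        file.path(out, "profiles_summary.json"),
        auto_unbox = TRUE, digits = NA)
      files <- c(files, file.path(out, "profiles_summary.json"))
      message("profiles: PC1+PC2 variance ",
              round(100 * sum(pca$variance_fraction[1:2]), 2), "%")
    }

    if ("structure" %in% stages) {
      stage <- "structure"
      mats <- stratum_coexpression(E)
      Ds <- correlation_distance_matrix(mats)
      dend <- average_linkage_cluster(Ds)
      sp <- top_split(dend)
      files <- c(files,
                 write_tsv(as.data.frame(unclass(Ds)),
                           file.path(out, "structure_distance.tsv")))
      jsonlite::write_json(list(top_split = sp),
                           file.path(out, "structure_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, file.path(out, "structure_summary.json"))
    }

    chain <- NULL
    if (any(c("diffcoex", "enrich", "rewire") %in% stages)) {
      stage <- "diffcoex"
      chain <- diffcoex_chain(E, beta = config$beta,
                              min_module_size = config$min_module_size,
                              deep_split = config$deep_split,
                              merge_r = config$merge_r)
      mods <- sort(setdiff(unique(chain$assignment), 0))
      message("diffcoex: ", length(mods), " modules (scale-free R2 = ",
              round(chain$scale_free_r2, 3), ")")
      rw <- chain$rewiring
      rw$p <- NA_real_
      for (i in seq_len(nrow(rw))) {
        g <- names(chain$assignment)[chain$assignment == rw$module[i]]
        rw$p[i] <- rewiring_permutation_test(
          E, g, n_perm = config$n_perm_module,
          seed = derive_seed(config$seed, rw$module[i]))$p
      }
      files <- c(files,
        write_tsv(data.frame(gene = names(chain$assignment),
                             module = unname(chain$assignment)),
                  file.path(out, "modules.tsv")),
        write_tsv(rw, file.path(out, "rewiring_stats.tsv")))
      if (!is.null(chain$eigengenes)) {
        eg <- chain$eigengenes$eigengenes
        files <- c(files,
          write_tsv(data.frame(sample_id = rownames(eg), eg,
                               check.names = FALSE),
                    file.path(out, "eigengenes.tsv")))
      }
    }

    if ("enrich" %in% stages && !is.null(config$gmt)) {
      stage <- "enrich"
      if (!file.exists(config$gmt)) stop("GMT not found: ", config$gmt)
      gsc <- read_gmt(config$gmt, background = gene_ids(E),
                      min_term_size = config$min_term_size)
      mods <- sort(setdiff(unique(chain$assignment), 0))
      enr <- lapply(mods, function(m) {
        g <- names(chain$assignment)[chain$assignment == m]
        tab <- zscore_enrichment(g, gsc,
                                 n_samples = config$n_samples_enrichment,
                                 alpha = config$alpha,
                                 seed = derive_seed(config$seed,
                                                    paste0("enr", m)))
        cbind(module = m, tab)
      })
      enr <- do.call(rbind, enr)
      files <- c(files, write_tsv(enr, file.path(out, "enrichment.tsv")))
      sig_sets <- split(enr$term[enr$significant], enr$module[enr$significant])
      sig_sets <- sig_sets[lengths(sig_sets) > 0]
      if (length(sig_sets) >= 2) {
        ex <- tf_exclusivity_test(sig_sets,
                                  motif_universe = names(gsc$sets),
                                  n_perm = config$n_perm_exclusivity,
                                  seed = config$seed)
        jsonlite::write_json(unclass(ex),
                             file.path(out, "exclusivity.json"),
                             auto_unbox = TRUE, digits = NA)
        oc <- overlap_counts(sig_sets)
        files <- c(files, file.path(out, "exclusivity.json"),
                   write_tsv(as.data.frame(oc$overlap),
                             file.path(out, "overlap_counts.tsv")))
      }
    }

    if ("rewire" %in% stages && !is.null(chain)) {
      stage <- "rewire"
      mods <- sort(setdiff(unique(chain$assignment), 0))
      for (m in mods) {
        g <- names(chain$assignment)[chain$assignment == m]
        ed <- classify_edges(chain$C_pre, chain$C_post, g,
                             threshold = config$edge_threshold)
        files <- c(files,
          export_graph(ed, file.path(out, sprintf("module_%s.graphml", m)),
                       "graphml"))
        deg <- degree_summary(ed)
        jsonlite::write_json(
          list(module = m, mean_degree_pre = deg$mean_degree_pre,
               mean_degree_post = deg$mean_degree_post,
               n_edges = nrow(ed)),
          file.path(out, sprintf("module_%s_degree.json", m)),
          auto_unbox = TRUE, digits = NA)
        files <- c(files, file.path(out, sprintf("module_%s_degree.json", m)))
      }
    }

    stage <- "manifest"
    files <- unique(files)
    manifest <- list(package = "coexshift",
                     version = as.character(utils::packageVersion("coexshift")),
                     parameters = unclass(config),
                     files = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    unlink(file.path(out, "FAILED"))
    invisible(manifest)
  }, error = on_fail)
}
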
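# Ground-truthed synthetic expression data with planted, condition-dependent
# coexpression modules.
#
# Model, per gene g and sample s:
#   x[g, s] = mu_g + rho[g, region(s)] + delta_g * 1[window(s) == 2]
#             + lambda_g(window(s)) * f[m(g), s] + eps,   eps ~ N(0, sd_g^2)
# with one latent factor f per module drawn i.i.d. N(0,1) per sample (no
# temporal autocorrelation: every downstream statistic is a cross-sample
# correlation). Rewiring archetypes are encoded in the window-specific
# loadings lambda:
#   gain    (0, L)            low correlation prenatally, high postnatally
#   loss    (L, 0)            the mirror image
#   stable  (L, L)            constant coexpression
#   swap    block A (L, cL), block B (-cL, L), c = `swap_minor`
#   background (0, 0)         pure noise
# The swap archetype reproduces the two-subnetwork rewiring pattern: block A
# is highly correlated prenatally only, block B postnatally only, and
# cross-block pairs flip from negative to positive correlation, which keeps
# the module a single connected block of the differential network.

#' Specify one planted module
#'
#' @param size number of genes (>= 1).
#' @param type rewiring archetype: `"gain"`, `"loss"`, `"swap"`, `"stable"`
#'   or `"background"`.
#' @param loading factor loading L in the high-correlation condition
#'   (default 1); the implied within-module correlation at loading L and
#'   noise sd s is L^2 / (L^2 + s^2).
#' @param swap_minor minor loading fraction c for swap modules (default 0.3):
#'   block A keeps a weak positive loading postnatally, block B a weak
#'   negative loading prenatally.
#' @param noise_sd residual standard deviation (> 0, default 0.3).
#' @param module_id optional label; defaults to `type` + running number.
#' @return a `ModuleSpec` list.
#' @export
module_spec <- function(size, type = c("gain", "loss", "swap", "stable",
                                       "background"),
                        loading = 1, swap_minor = 0.3, noise_sd = 0.3,
                        module_id = NULL) {
  type <- match.arg(type)
  stopifnot(size >= 1, noise_sd > 0, loading >= 0)
  structure(list(size = as.integer(size), type = type, loading = loading,
                 swap_minor = swap_minor, noise_sd = noise_sd,
                 module_id = module_id),
            class = "ModuleSpec")
}

#' Default planted-module design
#'
#' The stated test world used throughout the suite: two gain modules, one
#' loss, one swap and one stable module of 150 genes each, plus 1250
#' background genes (2000 genes total).
#'
#' @param module_size genes per planted module.
#' @param n_background background gene count.
#' @return list of [module_spec()]s.
#' @export
default_module_specs <- function(module_size = 150, n_background = 1250) {
  list(module_spec(module_size, "gain"),
       module_spec(module_size, "gain"),
       module_spec(module_size, "loss"),
       module_spec(module_size, "swap"),
       module_spec(module_size, "stable"),
       module_spec(n_background, "background"))
}

# Window-specific per-gene loadings for a spec; swap splits genes in halves.
spec_loadings <- function(spec) {
  n <- spec$size
  L <- spec$loading
  pre <- post <- numeric(n)
  block <- rep(NA_character_, n)
  switch(spec$type,
         gain = { post[] <- L },
         loss = { pre[] <- L },
         stable = { pre[] <- L; post[] <- L },
         background = { },
         swap = {
           a <- seq_len(ceiling(n / 2))
           b <- setdiff(seq_len(n), a)
           pre[a] <- L;                  post[a] <- spec$swap_minor * L
           pre[b] <- -spec$swap_minor * L; post[b] <- L
           block[a] <- "A"; block[b] <- "B"
         })
  list(pre = pre, post = post, block = block)
}

#' Simulate two-condition multi-region expression with planted modules
#'
#' @param specs list of [module_spec()]s; total genes = sum of sizes.
#' @param n_regions number of regions (default 8).
#' @param n_timepoints_per_window time points per window per region
#'   (default 7); total samples = `n_regions * n_timepoints_per_window * 2`.
#' @param region_effect_sd sd of the additive per-(gene, region) offset
#'   (default 0.3); gives profile clustering a recoverable region signal.
#' @param window_shift_sd sd of an additive per-gene postnatal mean shift
#'   (default 0); set > 0 to plant a global expression-level split between
#'   windows without touching within-window correlations.
#' @param n_de_genes number of planted differentially expressed genes
#'   (taken from background genes; default 0).
#' @param de_shift postnatal mean shift of planted DE genes, in units of the
#'   per-gene marginal sd (default 2).
#' @param base_mean,base_sd distribution of per-gene baselines mu_g
#'   (log-scale; defaults 6 and 1.5).
#' @param window_levels the two condition labels, ordered (pre, post).
#' @param exponentiate emit `2^x` instead of x, for nonnegative RPKM-like
#'   values (default FALSE).
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with elements `expression` (an [expression_matrix()]) and
#'   `truth`: a list with `genes` (data.frame gene/module/type/block),
#'   `modules` (data.frame module/type/size), `factors` (samples x modules
#'   latent factors), `loadings_pre`, `loadings_post`, `de_genes`.
#' @export
simulate_expression <- function(specs,
                                n_regions = 8,
                                n_timepoints_per_window = 7,
                                region_effect_sd = 0.3,
                                window_shift_sd = 0,
                                n_de_genes = 0,
                                de_shift = 2,
                                base_mean = 6, base_sd = 1.5,
                                window_levels = WINDOW_LEVELS_DEFAULT,
                                exponentiate = FALSE,
                                seed = 1L) {
  if (inherits(specs, "ModuleSpec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, n_regions >= 1, n_timepoints_per_window >= 1,
            length(window_levels) == 2)
  set.seed(as.integer(seed))

  # module bookkeeping
  types <- vapply(specs, `[[`, character(1), "type")
  counts <- table(types)
  tick <- setNames(integer(length(counts)), names(counts))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (is.null(sp$module_id)) {
      tick[sp$type] <- tick[sp$type] + 1L
      specs[[i]]$module_id <-
        if (counts[[sp$type]] > 1L) paste0(sp$type, tick[sp$type]) else sp$type
    }
  }
  mids <- vapply(specs, `[[`, character(1), "module_id")
  if (anyDuplicated(mids)) stop("duplicate module ids")
  sizes <- vapply(specs, `[[`, integer(1), "size")
  n_genes <- sum(sizes)
  genes <- sprintf("g%05d", seq_len(n_genes))

  # sample design
  regions <- sprintf("R%d", seq_len(n_regions))
  des <- expand.grid(t = seq_len(n_timepoints_per_window),
                     window = window_levels, region = regions,
                     stringsAsFactors = FALSE)
  des$window <- factor(des$window, levels = window_levels)
  n_samples <- nrow(des)
  samples <- data.frame(
    sample_id = sprintf("%s_%s_t%02d", des$region, as.character(des$window),
                        des$t),
    region = des$region,
    age = sprintf("%s%02d", ifelse(des$window == window_levels[1], "pre",
                                   "post"), des$t),
    window = as.character(des$window),
    stringsAsFactors = FALSE)
  is_post <- des$window == window_levels[2]

  # per-gene pieces
  mu <- rnorm(n_genes, base_mean, base_sd)
  rho <- matrix(rnorm(n_genes * n_regions, 0, region_effect_sd),
                n_genes, n_regions, dimnames = list(genes, regions))
  wshift <- if (window_shift_sd > 0) rnorm(n_genes, 0, window_shift_sd)
            else numeric(n_genes)

  # latent factors, loadings, noise
  fac <- matrix(rnorm(n_samples * length(specs)), n_samples, length(specs),
                dimnames = list(samples$sample_id, mids))
  lpre <- lpost <- numeric(n_genes)
  gmod <- character(n_genes); gtype <- character(n_genes)
  gblock <- rep(NA_character_, n_genes)
  nsd <- numeric(n_genes)
  off <- 0L
  X <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples$sample_id))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    idx <- off + seq_len(sp$size); off <- off + sp$size
    ld <- spec_loadings(sp)
    lpre[idx] <- ld$pre; lpost[idx] <- ld$post; gblock[idx] <- ld$block
    gmod[idx] <- sp$module_id; gtype[idx] <- sp$type; nsd[idx] <- sp$noise_sd
    lam <- outer(ld$pre, as.numeric(!is_post)) +
           outer(ld$post, as.numeric(is_post))
    X[idx, ] <- lam * matrix(fac[, i], sp$size, n_samples, byrow = TRUE)
  }
  X <- X + mu + rho[, match(des$region, regions)] +
       outer(wshift, as.numeric(is_post)) +
       matrix(rnorm(n_genes * n_samples), n_genes, n_samples) * nsd

  # planted DE genes: fixed postnatal shift in units of marginal sd
  de_genes <- character(0)
  if (n_de_genes > 0) {
    pool <- which(gtype == "background")
    if (length(pool) < n_de_genes) pool <- seq_len(n_genes)
    pick <- sort(sample(pool, n_de_genes))
    msd <- sqrt(nsd[pick]^2 + region_effect_sd^2 +
                  ((lpre[pick]^2 + lpost[pick]^2) / 2))
    X[pick, is_post] <- X[pick, is_post] + de_shift * msd
    de_genes <- genes[pick]
  }

  if (exponentiate) X <- 2^X

  truth <- list(
    genes = data.frame(gene = genes, module = gmod, type = gtype,
                       block = gblock, stringsAsFactors = FALSE),
    modules = data.frame(module = mids,
                         type = vapply(specs, `[[`, character(1), "type"),
                         size = sizes, stringsAsFactors = FALSE),
    factors = fac,
    loadings_pre = setNames(lpre, genes),
    loadings_post = setNames(lpost, genes),
    de_genes = de_genes,
    window_levels = window_levels,
    seed = as.integer(seed))
  list(expression = expression_matrix(X, samples), truth = truth)
}

#' Simulate a gene-set annotation (GMT) collection with planted enrichments
#'
#' Planted terms draw a fraction `purity` of their members from a single
#' planted module (enrichment by construction); decoy terms are uniform
#' draws from the whole gene universe.
#'
#' @param truth ground-truth component of [simulate_expression()] output.
#' @param n_terms total number of terms.
#' @param frac_planted fraction of terms planted inside modules (in \[0,1\]).
#' @param term_size_range inclusive bounds on term sizes (default c(150, 250)).
#' @param purity fraction of a planted term drawn from its module
#'   (default 0.9).
#' @param seed integer seed.
#' @return list with `collection` (a [gene_set_collection()]) and `planted`
#'   (data.frame term/module of the planted enrichments).
#' @export
simulate_annotations <- function(truth, n_terms, frac_planted = 0.3,
                                 term_size_range = c(150, 250),
                                 purity = 0.9, seed = 1L) {
  stopifnot(frac_planted >= 0, frac_planted <= 1,
            term_size_range[1] >= 1, length(term_size_range) == 2)
  universe <- truth$genes$gene
  if (term_size_range[2] > length(universe))
    stop("term sizes exceed the gene universe")
  set.seed(as.integer(seed))
  if (n_terms == 0)
    return(list(collection = gene_set_collection(list(), universe,
                                                 min_term_size = 1),
                planted = data.frame(term = character(0),
                                     module = character(0))))
  n_planted <- round(frac_planted * n_terms)
  planted_mods <- truth$modules$module[truth$modules$type != "background"]
  sets <- list(); planted <- data.frame(term = character(0),
                                        module = character(0))
  for (i in seq_len(n_terms)) {
    id <- sprintf("T%04d", i)
    size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
    if (i <= n_planted && length(planted_mods)) {
      mod <- planted_mods[1 + (i - 1) %% length(planted_mods)]
      mg <- truth$genes$gene[truth$genes$module == mod]
      k <- min(length(mg), round(purity * size))
      members <- c(sample(mg, k),
                   sample(setdiff(universe, mg), size - k))
      planted <- rbind(planted, data.frame(term = id, module = mod))
    } else {
      members <- sample(universe, size)
    }
    sets[[id]] <- members
  }
  list(collection = gene_set_collection(sets, universe,
                                        min_term_size = min(150,
                                          term_size_range[1])),
       planted = planted)
}

#' Write a simulated dataset to a directory
#'
#' Emits `expression.tsv`, `metadata.tsv`, `annotations.gmt` and
#' `truth.json`.
#'
#' @param sim output of [simulate_expression()].
#' @param out_dir output directory (created if absent).
#' @param annotations optional output of [simulate_annotations()].
#' @return invisibly, the written paths.
#' @export
write_simulation <- function(sim, out_dir, annotations = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_expression(sim$expression,
                            file.path(out_dir, "expression.tsv"),
                            file.path(out_dir, "metadata.tsv"))
  tr <- sim$truth
  tr$factors <- NULL                      # large and reconstructible by seed
  jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  paths <- c(paths, file.path(out_dir, "truth.json"))
  if (!is.null(annotations)) {
    write_gmt(annotations$collection, file.path(out_dir, "annotations.gmt"))
    paths <- c(paths, file.path(out_dir, "annotations.gmt"))
  }
  invisible(paths)
}
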
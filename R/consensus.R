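#' Parameters of the consensus module definition
#'
#' @param r_threshold correlation threshold for calling two clusters
#'   neighbors (strict `r >` this value; default 0.7).
#' @param min_neighbors minimum number of correlated neighbors for a cluster
#'   to be kept as recurrent (default 6; see [discover_modules()] for how the
#'   pipeline scales this to small compendia).
#' @param membership_fraction a gene enters a module's distilled set when it
#'   appears in strictly more than this fraction of the module's member
#'   clusters (default 1/3).
#' @param n_modules number of modules to cut the tree into, or `"auto"` to
#'   maximize the mean silhouette width over k = 2..min(15, n-1).
#' @return list of class `consensus_params`.
#' @export
consensus_params <- function(r_threshold = 0.7, min_neighbors = 6L,
                             membership_fraction = 1 / 3,
                             n_modules = "auto") {
  if (!is_prob(r_threshold)) stop_("r_threshold must be in (0, 1)")
  if (!is_count(min_neighbors)) stop_("min_neighbors must be >= 1")
  if (!is_prob(membership_fraction)) stop_("membership_fraction must be in (0,1)")
  if (!(identical(n_modules, "auto") || is_count(n_modules, 1L)))
    stop_("n_modules must be 'auto' or a positive integer")
  structure(list(r_threshold = r_threshold,
                 min_neighbors = as.integer(min_neighbors),
                 membership_fraction = membership_fraction,
                 linkage = "complete", distance = "euclidean",
                 n_modules = n_modules),
            class = "consensus_params")
}

#' Pairwise Pearson correlation between cluster score rows
#'
#' @param m a `cluster_score_matrix` from [score_compendium()] (>= 2 rows).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
cluster_score_correlations <- function(m) {
  if (nrow(m) < 2L) stop_("need at least 2 clusters")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0))
    stop_("zero-variance score row(s): ",
          paste(rownames(m)[sds == 0], collapse = ", "))
  stats::cor(t(unclass(m)))
}

#' Keep clusters that recur across datasets
#'
#' A cluster is retained when its metagene score correlates (strictly
#' `r > r_threshold`) with at least `min_neighbors` other clusters —
#' evidence that the same co-expression pattern was found independently in
#' several datasets.
#'
#' @param corr cluster score correlation matrix.
#' @param params a [consensus_params].
#' @return character vector of retained cluster ids.
#' @export
filter_recurrent_clusters <- function(corr, params = consensus_params()) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  deg <- rowSums(corr > params$r_threshold) - 1L  # exclude self (diag = 1)
  rownames(corr)[deg >= params$min_neighbors]
}

#' Aggregate recurrent clusters into consensus modules
#'
#' Hierarchically clusters the retained clusters using the rows of their
#' score-correlation submatrix as feature vectors (Euclidean distance,
#' complete linkage) and cuts the tree into `n_modules` groups. With
#' `n_modules = "auto"` the cut maximizing the mean silhouette width over
#' k = 2..min(15, n-1) is chosen; if the silhouette is degenerate (e.g. all
#' pairwise correlations identical) the cut falls back to k = 2 with a
#' warning. Modules are labeled `M1`, `M2`, ... by decreasing size.
#'
#' @param corr_sub correlation submatrix over the retained clusters (>= 2).
#' @param params a [consensus_params].
#' @return named character vector mapping cluster id -> module id.
#' @export
define_modules <- function(corr_sub, params = consensus_params()) {
  n <- nrow(corr_sub)
  if (is.null(n) || n < 2L) stop_("need at least 2 retained clusters")
  d <- stats::dist(corr_sub, method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  if (identical(params$n_modules, "auto")) {
    ks <- 2L:min(15L, n - 1L)
    if (length(ks) == 0L || n == 2L) {
      k_best <- 2L
    } else {
      sil <- vapply(ks, function(k) {
        cut <- stats::cutree(hc, k = k)
        if (length(unique(cut)) < 2L) return(NA_real_)
        s <- cluster::silhouette(cut, d)
        if (length(s) == 1L && is.na(s)) NA_real_ else mean(s[, "sil_width"])
      }, numeric(1))
      if (all(!is.finite(sil)) || max(sil, na.rm = TRUE) <= 0 ||
          stats::sd(as.matrix(d)) == 0) {
        warning("degenerate silhouette profile; falling back to k = 2",
                call. = FALSE)
        k_best <- 2L
      } else {
        k_best <- ks[which.max(sil)]
      }
    }
  } else {
    k_best <- min(params$n_modules, n)
  }
  cut <- stats::cutree(hc, k = k_best)
  sizes <- table(cut)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- stats::setNames(sprintf("M%d", seq_along(ord)),
                             names(sizes)[ord])
  stats::setNames(unname(relabel[as.character(cut)]), rownames(corr_sub))
}

#' Distill each module's consensus gene set
#'
#' A gene belongs to a module when it appears in strictly more than
#' `membership_fraction` of the module's member clusters, so genes found by
#' a single dataset's clustering do not enter the consensus.
#'
#' @param assignment named map cluster id -> module id from
#'   [define_modules()].
#' @param clusters list of `gene_cluster`s (superset of the assigned ones).
#' @param params a [consensus_params].
#' @return named list module id -> character vector of gene ids.
#' @export
module_gene_sets <- function(assignment, clusters,
                             params = consensus_params()) {
  cl_by_id <- stats::setNames(clusters,
                              vapply(clusters, `[[`, character(1), "cluster_id"))
  miss <- setdiff(names(assignment), names(cl_by_id))
  if (length(miss)) stop_("assigned clusters without gene lists: ",
                          paste(miss, collapse = ", "))
  out <- lapply(split(names(assignment), assignment), function(cids) {
    n_cl <- length(cids)
    freq <- table(unlist(lapply(cl_by_id[cids], `[[`, "gene_ids")))
    genes <- names(freq)[freq / n_cl > params$membership_fraction]
    if (length(genes) == 0L) {
      top <- utils::head(sort(freq, decreasing = TRUE), 5L)
      stop_("module over clusters {", paste(cids, collapse = ", "),
            "} has no gene in more than ",
            round(100 * params$membership_fraction, 1),
            "% of its clusters; top gene frequencies: ",
            paste(names(top), top, sep = "=", collapse = ", "))
    }
    sort(genes, method = "radix")
  })
  out[order(names(out))]
}

#' Compute a module's consensus gene weights
#'
#' Weights are the unit-norm PC1 of the module's gene set over the pooled
#' (column-concatenated, per-dataset z-scored) samples of the datasets that
#' contributed a member cluster, with the same sign convention as
#' [compute_metagene()]. A single-gene module gets weight 1 with a warning.
#'
#' @param gene_set character vector of module gene ids.
#' @param comp the preprocessed [compendium].
#' @param contributing_datasets dataset ids that contributed a member
#'   cluster; defaults to all datasets.
#' @param module_id module label carried into the result.
#' @return object of class `coex_module`: list with `module_id`, `gene_ids`,
#'   `weights` (named, unit norm), `contributing_datasets`.
#' @export
module_weights <- function(gene_set, comp,
                           contributing_datasets = names(comp$datasets),
                           module_id = "M1") {
  stopifnot(inherits(comp, "compendium"))
  miss <- setdiff(gene_set, comp$gene_universe)
  if (length(miss)) stop_("module genes absent from the gene universe: ",
                          paste(utils::head(miss, 5L), collapse = ", "))
  if (length(gene_set) < 2L) {
    warning("single-gene module '", module_id, "'; weight set to 1",
            call. = FALSE)
    w <- stats::setNames(1, gene_set)
  } else {
    pooled <- do.call(cbind, lapply(comp$datasets[contributing_datasets],
                                    function(d)
                                      d$values[gene_set, , drop = FALSE]))
    w <- pc1_weights(pooled)
  }
  structure(list(module_id = module_id, gene_ids = names(w), weights = w,
                 contributing_datasets = contributing_datasets),
            class = "coex_module")
}

#' Score a dataset for module activity
#'
#' Projects each sample's z-scored expression onto the module weight vector
#' (inner product over the module genes present in the dataset; absent genes
#' contribute nothing and the retained weight norm is reported, as in
#' [score_samples()]). For cross-platform data, collapse probes to gene
#' symbols by the median first (`collapse_map`) — the collapsed matrix is
#' re-z-scored before projection.
#'
#' @param module a `coex_module` (or a bare named weight vector).
#' @param ds an [expression_dataset]; must be z-scored unless `collapse_map`
#'   is given, in which case collapsing and z-scoring are applied here.
#' @param collapse_map optional named character vector probe id -> gene
#'   symbol for cross-platform scoring.
#' @return named per-sample numeric vector with attribute `retained_norm`.
#' @export
score_module <- function(module, ds, collapse_map = NULL) {
  w <- if (inherits(module, "coex_module")) module$weights else module
  if (!is.null(collapse_map)) {
    ds <- collapse_by_symbol(ds, collapse_map)
    ds <- zscore_genes(ds)
  }
  score_samples(w, ds)
}

#' Median-collapse probes to gene symbols
#'
#' @param ds an [expression_dataset] whose rownames are probe ids.
#' @param collapse_map named character vector probe id -> gene symbol.
#' @return an [expression_dataset] on gene symbols (median over probes).
#' @export
collapse_by_symbol <- function(ds, collapse_map) {
  stopifnot(inherits(ds, "expression_dataset"))
  probes <- intersect(gene_ids(ds), names(collapse_map))
  if (length(probes) == 0L) stop_("no probe of '", ds$dataset_id,
                                  "' appears in the collapse map")
  sym <- collapse_map[probes]
  v <- ds$values[probes, , drop = FALSE]
  med <- do.call(rbind, lapply(split(seq_along(probes), sym), function(i)
    apply(v[i, , drop = FALSE], 2L, stats::median)))
  expression_dataset(med, ds$dataset_id, ds$context)
}

#' Discover consensus modules in a preprocessed compendium
#'
#' Runs the full within-dataset and cross-dataset chain: per-dataset bimodal
#' gene detection, model-based gene clustering, PC1 metagenes, compendium
#' scoring, recurrence filtering, module definition, gene-set distillation
#' and consensus weights.
#'
#' By default `min_neighbors` is scaled to `min(params$min_neighbors,
#' n_datasets - 1)`: the recurrence filter asks for independent replication
#' across datasets, and a compendium of D datasets can support at most D - 1
#' replications of a pattern that appears once per dataset.
#'
#' @param comp a preprocessed [compendium].
#' @param params a [consensus_params].
#' @param fdr_threshold,null_draws,k_max,min_cluster_size,seed stage
#'   parameters (see the stage functions).
#' @param scale_min_neighbors scale `min_neighbors` to the compendium size
#'   as described above (default `TRUE`).
#' @return list of class `module_discovery` with elements `modules` (list of
#'   `coex_module`), `module_assignment`, `clusters`, `bimodality` (per
#'   dataset), `cluster_scores`, `score_correlations`, `retained_clusters`,
#'   `module_scores` (modules x compendium samples), `params`.
#' @export
discover_modules <- function(comp, params = consensus_params(),
                             fdr_threshold = 0.05, null_draws = 10000L,
                             k_max = 20L, min_cluster_size = 3L, seed = 0L,
                             scale_min_neighbors = TRUE) {
  stopifnot(inherits(comp, "compendium"))
  if (scale_min_neighbors) {
    eff <- min(params$min_neighbors, length(comp$datasets) - 1L)
    if (eff < params$min_neighbors)
      message("min_neighbors scaled to ", eff, " for a ",
              length(comp$datasets), "-dataset compendium")
    params$min_neighbors <- max(1L, eff)
  }
  bimod <- lapply(comp$datasets, function(d)
    select_bimodal_genes(d, fdr_threshold = fdr_threshold,
                         n_draws = null_draws, seed = seed))
  clusters <- list()
  for (d in comp$datasets) {
    tab <- bimod[[d$dataset_id]]
    sig <- tab$gene_id[tab$significant]
    cl <- cluster_bimodal_genes(d, sig, k_max = k_max,
                                min_cluster_size = min_cluster_size,
                                seed = seed)
    cl <- lapply(cl, compute_metagene, origin = d)
    clusters <- c(clusters, cl)
  }
  if (length(clusters) < 2L)
    stop_("fewer than 2 gene clusters discovered; cannot build modules")
  scores <- score_compendium(clusters, comp)
  corr <- cluster_score_correlations(scores)
  retained <- filter_recurrent_clusters(corr, params)
  if (length(retained) < 2L)
    stop_("fewer than 2 recurrent clusters after filtering (",
          length(retained), " retained)")
  assignment <- define_modules(corr[retained, retained, drop = FALSE], params)
  gene_sets <- module_gene_sets(assignment, clusters, params)
  cl_ds <- stats::setNames(vapply(clusters, `[[`, character(1),
                                  "source_dataset_id"),
                           vapply(clusters, `[[`, character(1), "cluster_id"))
  modules <- lapply(names(gene_sets), function(mid) {
    contrib <- sort(unique(unname(cl_ds[names(assignment)[assignment == mid]])))
    module_weights(gene_sets[[mid]], comp, contributing_datasets = contrib,
                   module_id = mid)
  })
  names(modules) <- names(gene_sets)
  mscores <- do.call(rbind, lapply(modules, function(m)
    unlist(lapply(comp$datasets, function(d) score_module(m, d)),
           use.names = FALSE)))
  colnames(mscores) <- colnames(scores)
  structure(list(modules = modules, module_assignment = assignment,
                 clusters = clusters, bimodality = bimod,
                 cluster_scores = scores, score_correlations = corr,
                 retained_clusters = retained, module_scores = mscores,
                 params = params),
            class = "module_discovery")
}

#' @export
print.module_discovery <- function(x, ...) {
  cat(sprintf("<module_discovery> %d clusters -> %d recurrent -> %d modules\n",
              length(x$clusters), length(x$retained_clusters),
              length(x$modules)))
  for (m in x$modules)
    cat(sprintf("  %s: %d genes (from %d clusters in %d datasets)\n",
                m$module_id, length(m$gene_ids),
                sum(x$module_assignment == m$module_id),
                length(m$contributing_datasets)))
  invisible(x)
}
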
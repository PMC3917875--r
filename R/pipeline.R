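#' Pipeline configuration
#'
#' All tunables of the end-to-end pipeline with their defaults. Serializable
#' to YAML with a lossless round trip.
#'
#' @param fdr_threshold bimodality FDR cutoff.
#' @param null_draws draws for the empirical BI null.
#' @param k_max,min_cluster_size gene-clustering controls.
#' @param r_threshold,min_neighbors,membership_fraction,n_modules consensus
#'   controls (see [consensus_params()]).
#' @param sigclust_sims simulations per SigClust test.
#' @param seed top-level seed; every stage derives its own sub-seed from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr_threshold = 0.05, null_draws = 10000L,
                            k_max = 20L, min_cluster_size = 3L,
                            r_threshold = 0.7, min_neighbors = 6L,
                            membership_fraction = 1 / 3, n_modules = "auto",
                            sigclust_sims = 1000L, seed = 0L) {
  if (!is_prob(fdr_threshold)) stop_("fdr_threshold must be in (0, 1)")
  if (!is_count(null_draws, 100L)) stop_("null_draws must be >= 100")
  if (!is_count(k_max, 2L)) stop_("k_max must be >= 2")
  if (!is_count(min_cluster_size, 2L)) stop_("min_cluster_size must be >= 2")
  if (!is_count(sigclust_sims, 100L)) stop_("sigclust_sims must be >= 100")
  cp <- consensus_params(r_threshold, min_neighbors, membership_fraction,
                         n_modules)
  structure(list(fdr_threshold = fdr_threshold,
                 null_draws = as.integer(null_draws),
                 k_max = as.integer(k_max),
                 min_cluster_size = as.integer(min_cluster_size),
                 r_threshold = cp$r_threshold,
                 min_neighbors = cp$min_neighbors,
                 membership_fraction = cp$membership_fraction,
                 n_modules = cp$n_modules,
                 sigclust_sims = as.integer(sigclust_sims),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path.
#' @return `read_pipeline_config`: a [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Run the full module-discovery pipeline
#'
#' preprocess -> bimodality -> gene clustering -> metagenes -> consensus
#' modules -> SigClust validation, writing all artifacts to `out_dir`:
#' preprocessed matrices, per-dataset bimodality tables, cluster membership
#' (TSV + GMT), cluster score matrix, module definitions (GMT + weights
#' TSV), module scores, pairwise SigClust tables, and a run manifest (YAML)
#' recording the config, seed and package versions. Rerunning with the same
#' inputs and seed reproduces every output byte-identically.
#'
#' @param input a [compendium] of raw datasets, or the path of a manifest
#'   TSV (see [read_manifest()]).
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if needed).
#' @param sigclust run the pairwise SigClust validation (default `TRUE`).
#' @return the `module_discovery` result, invisibly, with attribute
#'   `out_dir`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir,
                         sigclust = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(input)) {
    if (!file.exists(input)) stop_("missing manifest: ", input)
    input <- restrict_to_common_genes(read_manifest(input))
  }
  stopifnot(inherits(input, "compendium"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop_("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  comp <- stage("preprocess", preprocess_compendium(input))
  for (d in comp$datasets)
    write_expression_tsv(d, file.path(out_dir,
                                      paste0(d$dataset_id, "_preprocessed.tsv")))
  disc <- stage("discover", discover_modules(
    comp, consensus_params(config$r_threshold, config$min_neighbors,
                           config$membership_fraction, config$n_modules),
    fdr_threshold = config$fdr_threshold, null_draws = config$null_draws,
    k_max = config$k_max, min_cluster_size = config$min_cluster_size,
    seed = config$seed))
  stage("write", {
    for (id in names(disc$bimodality)) {
      tab <- disc$bimodality[[id]]
      tab[] <- lapply(tab, function(x) if (is.numeric(x))
        sprintf("%.10g", x) else x)
      utils::write.table(tab, file.path(out_dir,
                                        paste0(id, "_bimodality.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    memb <- do.call(rbind, lapply(disc$clusters, function(cl)
      data.frame(cluster_id = cl$cluster_id,
                 dataset_id = cl$source_dataset_id, gene_id = cl$gene_ids,
                 stringsAsFactors = FALSE)))
    utils::write.table(memb, file.path(out_dir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gmt(stats::setNames(lapply(disc$clusters, `[[`, "gene_ids"),
                              vapply(disc$clusters, `[[`, character(1),
                                     "cluster_id")),
              file.path(out_dir, "clusters.gmt"))
    sc <- disc$cluster_scores
    utils::write.table(data.frame(cluster_id = rownames(sc),
                                  apply(unclass(sc), 2L, sprintf,
                                        fmt = "%.10g"),
                                  check.names = FALSE),
                       file.path(out_dir, "cluster_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gmt(lapply(disc$modules, `[[`, "gene_ids"),
              file.path(out_dir, "modules.gmt"))
    write_weights_tsv(disc$modules, file.path(out_dir, "module_weights.tsv"))
    ms <- disc$module_scores
    utils::write.table(data.frame(module_id = rownames(ms),
                                  apply(ms, 2L, sprintf, fmt = "%.10g"),
                                  check.names = FALSE),
                       file.path(out_dir, "module_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  if (sigclust && length(disc$modules) >= 2L) {
    stage("sigclust", {
      for (method in c("hard", "soft")) {
        tab <- pairwise_module_sigclust(
          disc$module_assignment,
          disc$score_correlations[disc$retained_clusters,
                                  disc$retained_clusters, drop = FALSE],
          method = method, n_sims = config$sigclust_sims,
          seed = derive_seed(config$seed, "sigclust", method))
        tab$ci <- sprintf("%.10g", tab$ci)
        tab$p_value <- sprintf("%.10g", tab$p_value)
        utils::write.table(tab,
                           file.path(out_dir,
                                     paste0("sigclust_", method, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }
  manifest <- list(config = unclass(config),
                   datasets = names(comp$datasets),
                   n_modules_found = length(disc$modules),
                   package_version = as.character(utils::packageVersion("coexmod")))
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  attr(disc, "out_dir") <- out_dir
  invisible(disc)
}
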
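# small fixture builders shared across test files

random_dataset <- function(n_genes = 20, n_samples = 30, seed = 1,
                           dataset_id = "ds1", context = "tumor") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expression_dataset(m, dataset_id, context)
}

# a small two-module compendium used by several cross-stage tests
small_sim <- function(seed = 7, n_datasets = 3, n_samples = 60,
                      n_genes = 120, contexts = rep("tumor", n_datasets),
                      extrinsic2 = FALSE) {
  cfg <- simulation_config(
    n_datasets = n_datasets, contexts = contexts, n_genes = n_genes,
    n_samples = n_samples,
    modules = list(planted_module("modA", 15),
                   planted_module("modB", 15, extrinsic = extrinsic2)),
    quality_sd = 0.5, noise_sd = 1, seed = seed)
  generate_compendium(cfg)
}

# shared small empirical null so test files do not each pay for one
shared_null <- local({
  cache <- new.env()
  function(n, draws = 2000L) {
    key <- paste0(n, "_", draws)
    if (is.null(cache[[key]]))
      cache[[key]] <- null_bi_distribution(n, n_draws = draws, seed = 424242)
    cache[[key]]
  }
})
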
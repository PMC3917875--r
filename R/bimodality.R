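#' Fit a two-component equal-variance Gaussian mixture to one gene
#'
#' Maximum-likelihood EM fit of `pi * N(mu1, sigma^2) + (1 - pi) *
#' N(mu2, sigma^2)` with a common within-component variance, the model
#' underlying the Bimodality Index. The best of `n_restarts` initializations
#' is kept: the first places the component means at the 25th/75th percentiles
#' with pi = 0.5, the rest at random quantile positions with random pi drawn
#' from a local RNG stream seeded by `seed`, so the fit is reproducible and
#' independent of the caller's RNG state. Convergence means a log-likelihood
#' change below 1e-8 within 1,000 iterations. By convention `mu1 <= mu2` and
#' `pi` is the weight of the lower component.
#'
#' @param x numeric vector, length >= 10, nonzero variance.
#' @param n_restarts number of EM initializations (default 10).
#' @param seed integer seed for the restart initializations.
#' @return list of class `mixture_fit`: `pi`, `mu1`, `mu2`, `sigma`,
#'   `loglik`, `converged`.
#' @export
fit_two_component <- function(x, n_restarts = 10L, seed = 0L) {
  if (length(x) < 10L) stop_("need at least 10 observations")
  if (anyNA(x)) stop_("missing values in x")
  if (stats::sd(x) == 0) stop_("zero-variance input")
  init <- restart_inits(n_restarts, 1L, seed)
  fit <- .fit_mix_batch(matrix(x, ncol = 1L), init$q1, init$q2, init$pi)
  as_mixture_fit(fit[1L, ])
}

as_mixture_fit <- function(row) {
  structure(list(pi = unname(row["pi"]), mu1 = unname(row["mu1"]),
                 mu2 = unname(row["mu2"]), sigma = unname(row["sigma"]),
                 loglik = unname(row["loglik"]),
                 converged = unname(row["converged"]) > 0),
            class = "mixture_fit")
}

# restart initializations for G genes: quantile positions for the two means
# plus mixing proportions. First restart is the fixed quartile start.
restart_inits <- function(n_restarts, G, seed) {
  with_seed(seed, {
    q1 <- matrix(stats::runif(n_restarts * G, 0.02, 0.98), n_restarts, G)
    q2 <- matrix(stats::runif(n_restarts * G, 0.02, 0.98), n_restarts, G)
    pi <- matrix(stats::runif(n_restarts * G, 0.2, 0.8), n_restarts, G)
    q1[1L, ] <- 0.25; q2[1L, ] <- 0.75; pi[1L, ] <- 0.5
    list(q1 = pmin(q1, q2), q2 = pmax(q1, q2), pi = pi)
  })
}

#' Bimodality Index of a mixture fit
#'
#' `BI = sqrt(pi * (1 - pi)) * |mu2 - mu1| / sigma`. Large values indicate a
#' clear on/off expression pattern; the statistic is invariant to location
#' and scale and symmetric in the two components.
#'
#' @param fit a `mixture_fit` from [fit_two_component()], or any list with
#'   elements `pi`, `mu1`, `mu2`, `sigma`.
#' @return nonnegative scalar.
#' @export
bimodality_index <- function(fit) {
  stopifnot(is.list(fit), fit$sigma > 0, fit$pi > 0, fit$pi < 1)
  sqrt(fit$pi * (1 - fit$pi)) * abs(fit$mu2 - fit$mu1) / fit$sigma
}

#' Simulated null distribution of the Bimodality Index
#'
#' Draws `n_draws` standard-normal samples of size `n`, fits each with
#' [fit_two_component()] and records the BI. Because BI is location- and
#' scale-free, standard normals suffice for any unimodal Gaussian null. One
#' distribution is needed per distinct dataset size; results are cached per
#' session (keyed by `n`, `n_draws`, `seed`, `n_restarts`).
#'
#' @param n sample size the null is built for (>= 10).
#' @param n_draws number of null draws (default 10,000).
#' @param seed integer seed.
#' @param n_restarts EM restarts per draw, matching the observed fits.
#' @return object of class `null_bi_distribution`: list with sorted `values`,
#'   `n`, `n_draws`, `seed`.
#' @export
null_bi_distribution <- function(n, n_draws = 10000L, seed = 0L,
                                 n_restarts = 10L) {
  if (!is_count(n, 10L)) stop_("n must be an integer >= 10")
  if (!is_count(n_draws)) stop_("n_draws must be a positive integer")
  key <- paste(n, n_draws, seed, n_restarts, sep = "_")
  cached <- .null_cache[[key]]
  if (!is.null(cached)) return(cached)
  fits <- with_seed(derive_seed(seed, "null_bi", n, n_draws), {
    X <- matrix(stats::rnorm(n * n_draws), n, n_draws)
    init <- restart_inits(n_restarts, n_draws,
                          derive_seed(seed, "null_bi_init", n, n_draws))
    .fit_mix_batch(X, init$q1, init$q2, init$pi)
  })
  bi <- sqrt(fits[, "pi"] * (1 - fits[, "pi"])) *
    abs(fits[, "mu2"] - fits[, "mu1"]) / fits[, "sigma"]
  out <- structure(list(values = sort(bi), n = as.integer(n),
                        n_draws = as.integer(n_draws), seed = as.integer(seed)),
                   class = "null_bi_distribution")
  .null_cache[[key]] <- out
  out
}

.null_cache <- new.env(parent = emptyenv())

#' Empirical p-value of an observed Bimodality Index
#'
#' Add-one empirical tail probability `p = (1 + #\{null >= bi\}) /
#' (n_draws + 1)`, the standard permutation-test convention that avoids
#' p = 0. Vectorized over `bi_obs`.
#'
#' @param bi_obs observed BI value(s).
#' @param null a `null_bi_distribution`.
#' @return p-value(s) in (0, 1].
#' @export
empirical_p <- function(bi_obs, null) {
  stopifnot(inherits(null, "null_bi_distribution"),
            length(null$values) > 0)
  B <- length(null$values)
  # count of null values >= bi via position in the sorted null
  n_ge <- B - findInterval(bi_obs, null$values, left.open = TRUE)
  (1 + n_ge) / (B + 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (a validated wrapper around
#' `stats::p.adjust(method = "BH")`); inputs must be in (0, 1].
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) stop_("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Score every gene of a dataset for significant bimodality
#'
#' Fits the two-component mixture to each gene, computes the Bimodality
#' Index, derives an empirical p-value against the simulated null for this
#' dataset's sample size, and adjusts across genes (within this dataset) by
#' Benjamini-Hochberg. Restart initializations are seeded per gene from a
#' hash of (dataset id, gene id), so results do not depend on gene order.
#'
#' @param ds a preprocessed [expression_dataset].
#' @param fdr_threshold FDR significance cutoff (default 0.05).
#' @param null optional precomputed [null_bi_distribution()] for
#'   `ncol(ds$values)`; built (and cached) if missing.
#' @param n_draws,seed,n_restarts forwarded to [null_bi_distribution()] and
#'   the per-gene fits.
#' @return data.frame of class `bimodality_table` with one row per gene
#'   (`gene_id`, `pi`, `mu1`, `mu2`, `sigma`, `bi`, `p_emp`, `q`,
#'   `significant`), sorted by `q` then `gene_id`.
#' @export
select_bimodal_genes <- function(ds, fdr_threshold = 0.05, null = NULL,
                                 n_draws = 10000L, seed = 0L,
                                 n_restarts = 10L) {
  stopifnot(inherits(ds, "expression_dataset"))
  n <- ncol(ds$values)
  G <- nrow(ds$values)
  if (G == 0L) {
    out <- data.frame(gene_id = character(0), pi = numeric(0),
                      mu1 = numeric(0), mu2 = numeric(0), sigma = numeric(0),
                      bi = numeric(0), p_emp = numeric(0), q = numeric(0),
                      significant = logical(0))
    class(out) <- c("bimodality_table", "data.frame")
    return(out)
  }
  if (is.null(null)) null <- null_bi_distribution(n, n_draws, seed, n_restarts)
  if (null$n != n) stop_("null distribution was built for n = ", null$n,
                         " but dataset has ", n, " samples")
  # per-gene deterministic restart seeds: order-independent reproducibility
  ids <- rownames(ds$values)
  q1 <- matrix(0, n_restarts, G); q2 <- q1; pp <- q1
  for (g in seq_len(G)) {
    init <- restart_inits(n_restarts, 1L,
                          derive_seed(seed, "fit", ds$dataset_id, ids[g]))
    q1[, g] <- init$q1; q2[, g] <- init$q2; pp[, g] <- init$pi
  }
  fits <- .fit_mix_batch(t(ds$values), q1, q2, pp)
  bi <- sqrt(fits[, "pi"] * (1 - fits[, "pi"])) *
    abs(fits[, "mu2"] - fits[, "mu1"]) / fits[, "sigma"]
  p <- empirical_p(bi, null)
  q <- bh_fdr(p)
  out <- data.frame(gene_id = ids, pi = fits[, "pi"], mu1 = fits[, "mu1"],
                    mu2 = fits[, "mu2"], sigma = fits[, "sigma"], bi = bi,
                    p_emp = p, q = q, significant = q < fdr_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("bimodality_table", "data.frame")
  out
}
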
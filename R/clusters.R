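#' Organize bimodal genes into co-expression clusters
#'
#' Treats each significantly bimodal gene as an observation whose features
#' are its standardized across-sample profile, and fits Gaussian mixtures
#' for k = 1..min(k_max, floor(G / min_cluster_size)) under spherical
#' (per-component `sigma^2 I`) and diagonal (per-component axis-wise)
#' covariance families. The (k, family) pair maximizing
#' `BIC = loglik - (n_params / 2) * log(G)` is selected (ties toward smaller
#' k), genes are hard-assigned by maximum posterior, clusters smaller than
#' `min_cluster_size` are discarded with a warning, and the survivors are
#' ordered by size (descending). Each EM run is the best of `n_restarts`
#' k-means++-style seedings drawn from a stream seeded by the dataset id, so
#' results are reproducible and invariant to gene order up to cluster labels.
#'
#' @param ds a preprocessed [expression_dataset].
#' @param bimodal_genes character vector of gene ids to cluster (typically
#'   the significant rows of [select_bimodal_genes()]).
#' @param k_max maximum number of clusters considered (default 20).
#' @param min_cluster_size minimum genes per retained cluster (default 3;
#'   within-cluster PC1 needs at least 3 genes to be meaningful).
#' @param n_restarts EM seedings per (k, family) (default 5).
#' @param seed integer seed.
#' @return list of `gene_cluster` objects, each a list with `cluster_id`,
#'   `source_dataset_id`, `gene_ids`, and `metagene` (`NULL` until
#'   [compute_metagene()] fills it). Attribute `selection` records the BIC
#'   table. Empty list (with a warning) if fewer than `min_cluster_size`
#'   bimodal genes are supplied.
#' @export
cluster_bimodal_genes <- function(ds, bimodal_genes, k_max = 20L,
                                  min_cluster_size = 3L, n_restarts = 5L,
                                  seed = 0L) {
  stopifnot(inherits(ds, "expression_dataset"))
  bimodal_genes <- as.character(bimodal_genes)
  missing <- setdiff(bimodal_genes, gene_ids(ds))
  if (length(missing))
    stop_("genes not present in dataset: ",
          paste(utils::head(missing, 5L), collapse = ", "))
  G <- length(bimodal_genes)
  if (G < min_cluster_size) {
    warning("only ", G, " bimodal gene(s) in '", ds$dataset_id,
            "'; need at least ", min_cluster_size, " - no clusters formed",
            call. = FALSE)
    return(list())
  }
  # canonical gene order so clustering is invariant to input order
  bimodal_genes <- sort(bimodal_genes, method = "radix")
  X <- ds$values[bimodal_genes, , drop = FALSE]
  ks <- seq_len(min(k_max, G %/% min_cluster_size))
  fams <- c("spherical", "diagonal")
  best <- NULL
  sel <- NULL
  for (fam in fams) {
    for (k in ks) {
      fit <- gmm_best_fit(X, k, fam, n_restarts,
                          derive_seed(seed, "gmm", ds$dataset_id, fam, k))
      if (is.null(fit)) next  # no non-degenerate solution at this (k, family)
      d <- ncol(X)
      n_par <- (k - 1) + k * d + switch(fam, spherical = k, diagonal = k * d)
      bic <- fit$loglik - n_par / 2 * log(G)
      sel <- rbind(sel, data.frame(family = fam, k = k, loglik = fit$loglik,
                                   n_params = n_par, bic = bic))
      # strict > keeps the first (smallest-k) maximizer on ties
      if (is.null(best) || bic > best$bic + 1e-9)
        best <- list(fit = fit, bic = bic, k = k, family = fam)
    }
  }
  assign <- max.col(best$fit$z, ties.method = "first")
  sizes <- tabulate(assign, nbins = best$k)
  keep <- which(sizes >= min_cluster_size)
  if (length(keep) < best$k)
    warning(best$k - length(keep), " cluster(s) smaller than ",
            min_cluster_size, " discarded in '", ds$dataset_id, "'",
            call. = FALSE)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  clusters <- lapply(seq_along(keep), function(i) {
    structure(list(cluster_id = sprintf("%s.c%02d", ds$dataset_id, i),
                   source_dataset_id = ds$dataset_id,
                   gene_ids = bimodal_genes[assign == keep[i]],
                   metagene = NULL),
              class = "gene_cluster")
  })
  attr(clusters, "selection") <- sel
  clusters
}

# best-of-restarts GMM fit with k-means++-style seeding; restarts are
# screened at a loose tolerance and the winner polished at the final one
gmm_best_fit <- function(X, k, family, n_restarts, seed) {
  best <- NULL
  centers_list <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) kmeanspp_centers(X, k))
  })
  spher <- family == "spherical"
  for (centers in centers_list) {
    fit <- .gmm_diag_em(X, centers, spher, tol = 1e-4, maxit = 60L)
    if (fit$degenerate) next  # collapsed component: not a valid ML solution
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) return(NULL)  # every restart degenerate at this (k, family)
  polished <- .gmm_diag_em(X, best$mean, spher, tol = 1e-7, maxit = 500L)
  if (!polished$degenerate && polished$loglik >= best$loglik) polished else best
}

# classic k-means++ seeding: first center uniform, later centers with
# probability proportional to squared distance to the nearest chosen center
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, X[idx[1L], ], "-")^2)
    for (j in 2L:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1L, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[j], ], "-")^2))
    }
  }
  X[idx, , drop = FALSE]
}
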
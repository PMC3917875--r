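#' Compute a cluster's PC1 metagene in its origin dataset
#'
#' The metagene is the unit-norm first principal axis of the cluster's
#' genes x samples submatrix with genes as variables (gene rows are z-scored,
#' so this is a correlation-style PCA). The sign is oriented so that the sum
#' over member genes of the Pearson correlation between each gene and the
#' projected sample score is positive; on an exact tie the sign of the first
#' gene's weight is made positive, with a warning.
#'
#' @param cluster a `gene_cluster` (see [cluster_bimodal_genes()]).
#' @param origin the preprocessed [expression_dataset] the cluster came from.
#' @return the cluster with `metagene` filled (named weight vector, unit
#'   Euclidean norm).
#' @export
compute_metagene <- function(cluster, origin) {
  stopifnot(inherits(cluster, "gene_cluster"),
            inherits(origin, "expression_dataset"))
  miss <- setdiff(cluster$gene_ids, gene_ids(origin))
  if (length(miss)) stop_("cluster genes absent from origin dataset: ",
                          paste(utils::head(miss, 5L), collapse = ", "))
  X <- origin$values[cluster$gene_ids, , drop = FALSE]
  cluster$metagene <- pc1_weights(X)
  cluster
}

# unit-norm first principal axis of gene-rows-as-variables, with the
# correlation-sum sign convention
pc1_weights <- function(X) {
  sv <- svd(X, nu = 1L, nv = 0L)
  w <- drop(sv$u)
  score <- drop(crossprod(w, X))
  or <- sum(apply(X, 1L, function(row) suppressWarnings(stats::cor(row, score))),
            na.rm = TRUE)
  if (abs(or) < 1e-12) {
    warning("degenerate PC1 orientation; using the first gene's weight sign",
            call. = FALSE)
    or <- if (w[1L] != 0) w[1L] else 1
  }
  if (or < 0) w <- -w
  stats::setNames(w, rownames(X))
}

#' Project a dataset's samples onto a metagene
#'
#' The score of a sample is the inner product between its normalized
#' expression and the metagene weights, restricted to the metagene genes
#' present in the dataset: absent genes simply contribute nothing and the
#' weights are not renormalized, so scores from platforms with partial gene
#' coverage stay on a comparable scale. The Euclidean norm of the retained
#' weights is attached as attribute `retained_norm` (a warning is raised
#' below 0.5).
#'
#' @param metagene a `gene_cluster` with `metagene` filled, or a bare named
#'   weight vector.
#' @param ds a z-scored (and quality-adjusted) [expression_dataset].
#' @return named per-sample numeric vector with attribute `retained_norm`.
#' @export
score_samples <- function(metagene, ds) {
  w <- if (inherits(metagene, "gene_cluster")) metagene$metagene else metagene
  if (is.null(w) || is.null(names(w)))
    stop_("metagene weights missing; call compute_metagene() first")
  stopifnot(inherits(ds, "expression_dataset"))
  present <- intersect(names(w), gene_ids(ds))
  if (length(present) == 0L)
    stop_("no metagene gene present in dataset '", ds$dataset_id, "'")
  retained <- sqrt(sum(w[present]^2)) / sqrt(sum(w^2))
  if (retained < 0.5)
    warning(sprintf("only %.2f of the weight norm is represented in '%s'",
                    retained, ds$dataset_id), call. = FALSE)
  s <- drop(crossprod(ds$values[present, , drop = FALSE], w[present]))
  names(s) <- sample_ids(ds)
  attr(s, "retained_norm") <- retained
  s
}

#' Score every sample of a compendium against every cluster
#'
#' Each dataset is scored independently (datasets are normalized
#' independently throughout), producing the clusters x samples score matrix
#' whose column names are `dataset_id:sample_id` keys.
#'
#' @param clusters list of `gene_cluster`s with metagenes filled.
#' @param comp a preprocessed [compendium].
#' @return numeric matrix of class `cluster_score_matrix` (clusters x
#'   samples) with rownames = cluster ids.
#' @export
score_compendium <- function(clusters, comp) {
  stopifnot(inherits(comp, "compendium"), length(clusters) >= 1L)
  ids <- vapply(clusters, `[[`, character(1), "cluster_id")
  cols <- unlist(lapply(comp$datasets, function(d)
    paste(d$dataset_id, sample_ids(d), sep = ":")), use.names = FALSE)
  scores <- matrix(NA_real_, length(clusters), length(cols),
                   dimnames = list(ids, cols))
  for (d in comp$datasets) {
    key <- paste(d$dataset_id, sample_ids(d), sep = ":")
    for (i in seq_along(clusters))
      scores[i, key] <- score_samples(clusters[[i]], d)
  }
  stopifnot(!anyNA(scores))
  class(scores) <- c("cluster_score_matrix", class(scores))
  scores
}
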
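#' Restrict datasets to their common gene universe
#'
#' Intersects the gene id sets of all datasets, sorts the intersection
#' lexicographically (locale-independent C ordering) and row-subsets every
#' dataset to it, yielding a [compendium] on a shared universe.
#'
#' @param datasets list of [expression_dataset] objects (each with >= 2 genes).
#' @return a [compendium].
#' @export
restrict_to_common_genes <- function(datasets) {
  if (length(datasets) < 1L) stop_("need at least one dataset")
  for (d in datasets)
    if (nrow(d$values) < 2L)
      stop_("dataset '", d$dataset_id, "' has fewer than 2 genes")
  universe <- Reduce(intersect, lapply(datasets, gene_ids))
  if (length(universe) == 0L)
    stop_("empty gene intersection across datasets: ",
          paste(vapply(datasets, `[[`, character(1), "dataset_id"),
                collapse = ", "))
  universe <- sort(universe, method = "radix")
  datasets <- lapply(datasets, function(d) {
    expression_dataset(d$values[universe, , drop = FALSE], d$dataset_id,
                       d$context,
                       avg_z = d$avg_z)
  })
  compendium(datasets)
}

# z-score rows of a matrix with the sample (n-1) sd; returns NULL rows kept
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  sweep(sweep(m, 1L, mu, "-"), 1L, sd, "/")
}

#' Z-score normalize each gene of a dataset
#'
#' Centers and scales every gene row to mean 0 and sample (n-1 denominator)
#' standard deviation 1. Genes with zero variance carry no co-expression
#' signal and corrupt downstream mixture fits, so they are dropped with a
#' warning rather than kept as all-zero rows.
#'
#' @param ds an [expression_dataset] with at least 3 samples.
#' @return the z-scored [expression_dataset] (possibly with fewer genes).
#' @export
zscore_genes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ncol(ds$values) < 3L)
    stop_("dataset '", ds$dataset_id,
          "' has fewer than 3 samples; sd is ill-determined")
  sds <- apply(ds$values, 1L, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sum(drop), " zero-variance gene(s) dropped from '",
            ds$dataset_id, "': ",
            paste(utils::head(rownames(ds$values)[drop], 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ..." else "", call. = FALSE)
  }
  if (all(drop)) stop_("all genes in '", ds$dataset_id, "' have zero variance")
  v <- ds$values[!drop, , drop = FALSE]
  expression_dataset(zscore_rows(v), ds$dataset_id, ds$context,
                     avg_z = ds$avg_z)
}

#' Compute the per-array quality score avg.z
#'
#' The quality score of a sample is the mean over genes of its z-scored
#' expression: technically poor arrays shift all genes together, so their
#' mean z-score departs from 0. The score is stored on the dataset for
#' subsequent residualization by [quality_adjust()].
#'
#' @param ds a z-scored [expression_dataset].
#' @return the dataset with `avg_z` filled (named per-sample numeric vector).
#' @export
compute_avg_z <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  ds$avg_z <- colMeans(ds$values)
  ds
}

#' Residualize expression on array quality
#'
#' Replaces every gene row with the ordinary-least-squares residual of that
#' row regressed on (intercept, avg_z), removing spurious gene-gene
#' correlation induced by array-quality differences. Each output row has mean
#' 0 and correlation with avg_z below 1e-8. Idempotent. If avg_z is constant
#' the regression is undefined and the data are returned unchanged with a
#' warning.
#'
#' @param ds an [expression_dataset] with `avg_z` computed (see
#'   [compute_avg_z()]).
#' @return the quality-adjusted [expression_dataset] (avg_z retained).
#' @export
quality_adjust <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$avg_z)) stop_("avg_z not computed; call compute_avg_z() first")
  z <- ds$avg_z
  if (stats::sd(z) == 0) {
    warning("avg_z is constant in '", ds$dataset_id,
            "'; quality adjustment skipped", call. = FALSE)
    return(ds)
  }
  X <- cbind(1, z)
  # residual projection, applied to all gene rows at once
  coef <- solve(crossprod(X), crossprod(X, t(ds$values)))
  res <- ds$values - t(X %*% coef)
  expression_dataset(res, ds$dataset_id, ds$context, avg_z = ds$avg_z)
}

#' Full per-dataset preprocessing chain
#'
#' Applies the standard sequence: z-score each gene, compute the avg.z array
#' quality score, residualize expression on it, and re-z-score so downstream
#' projections operate on unit-variance rows. Genes that lose all variance
#' are dropped with a warning.
#'
#' @param ds raw [expression_dataset] (log2 scale).
#' @return preprocessed [expression_dataset] with `avg_z` attached.
#' @export
preprocess_dataset <- function(ds) {
  ds <- zscore_genes(ds)
  ds <- compute_avg_z(ds)
  ds <- quality_adjust(ds)
  # re-z-score the residuals (avg_z retained from the pre-adjustment pass)
  sds <- apply(ds$values, 1L, stats::sd)
  keep <- sds > 0 & is.finite(sds)
  if (!all(keep))
    warning(sum(!keep), " gene(s) with zero residual variance dropped from '",
            ds$dataset_id, "'", call. = FALSE)
  v <- zscore_rows(ds$values[keep, , drop = FALSE])
  expression_dataset(v, ds$dataset_id, ds$context, avg_z = ds$avg_z)
}

#' Preprocess every dataset of a compendium
#'
#' Runs [preprocess_dataset()] on each member dataset and re-restricts to the
#' genes surviving preprocessing in all datasets, so the compendium stays on
#' a single universe.
#'
#' @param comp a [compendium] of raw datasets.
#' @return a preprocessed [compendium].
#' @export
preprocess_compendium <- function(comp) {
  stopifnot(inherits(comp, "compendium"))
  restrict_to_common_genes(lapply(comp$datasets, preprocess_dataset))
}
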
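#' Expression dataset container
#'
#' One dataset's genes x samples log2-scale expression matrix together with
#' its identity, biological context and (once computed) the per-array quality
#' score `avg_z`. Gene and sample ids live in the matrix dimnames.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids, unique),
#'   samples in columns (colnames = sample ids, unique); log2 scale.
#' @param dataset_id single string.
#' @param context one of `"tumor"`, `"cell_line"`, `"mixed"`.
#' @param avg_z optional per-sample numeric vector of array quality scores.
#' @return an object of class `expression_dataset`: a list with elements
#'   `values`, `dataset_id`, `context`, `avg_z`.
#' @export
expression_dataset <- function(values, dataset_id, context = "tumor",
                               avg_z = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_("`values` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop_("duplicate gene ids in dataset '", dataset_id, "'")
  if (anyDuplicated(colnames(values)))
    stop_("duplicate sample ids in dataset '", dataset_id, "'")
  if (anyNA(values))
    stop_("missing values in dataset '", dataset_id, "'")
  if (!(length(dataset_id) == 1L && is.character(dataset_id)))
    stop_("`dataset_id` must be a single string")
  context <- match.arg(context, c("tumor", "cell_line", "mixed"))
  if (!is.null(avg_z)) {
    if (length(avg_z) != ncol(values))
      stop_("`avg_z` length must equal the number of samples")
    avg_z <- stats::setNames(as.numeric(avg_z), colnames(values))
  }
  structure(list(values = values, dataset_id = dataset_id,
                 context = context, avg_z = avg_z),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s [%s]: %d genes x %d samples%s\n",
              x$dataset_id, x$context, nrow(x$values), ncol(x$values),
              if (is.null(x$avg_z)) "" else ", avg_z computed"))
  invisible(x)
}

gene_ids <- function(ds) rownames(ds$values)
sample_ids <- function(ds) colnames(ds$values)

#' Compendium of expression datasets on a shared gene universe
#'
#' @param datasets list of [expression_dataset] objects whose gene id sets are
#'   all identical and in identical order.
#' @return an object of class `compendium`: list with `datasets` (named by
#'   dataset id) and `gene_universe`.
#' @seealso [restrict_to_common_genes()] to build one from heterogeneous
#'   datasets.
#' @export
compendium <- function(datasets) {
  if (length(datasets) < 1L) stop_("need at least one dataset")
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  if (anyDuplicated(ids)) stop_("duplicate dataset ids: ",
                                paste(ids[duplicated(ids)], collapse = ", "))
  universe <- gene_ids(datasets[[1]])
  for (d in datasets) {
    if (!identical(gene_ids(d), universe))
      stop_("dataset '", d$dataset_id,
            "' is not on the shared gene universe; use restrict_to_common_genes()")
  }
  names(datasets) <- ids
  structure(list(datasets = datasets, gene_universe = universe),
            class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("<compendium> %d datasets, %d genes\n",
              length(x$datasets), length(x$gene_universe)))
  for (d in x$datasets) print(d)
  invisible(x)
}
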
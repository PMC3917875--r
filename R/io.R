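#' Read a genes x samples expression TSV
#'
#' Expected dialect: tab-separated, UTF-8, no quoting; header row of sample
#' ids; first column named `gene_id`. Ragged rows and duplicate gene or
#' sample ids are rejected with the offending line numbers.
#'
#' @param path file path.
#' @param dataset_id dataset id (defaults to the file name without
#'   extension).
#' @param context dataset context.
#' @return an [expression_dataset].
#' @export
read_expression_tsv <- function(path, dataset_id = NULL, context = "tumor") {
  if (!file.exists(path)) stop_("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop_("ragged TSV '", path, "': line(s) ",
          paste(utils::head(which(nf != nf[1L]), 5L), collapse = ", "),
          " have a different field count")
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "gene_id")
    stop_("first column of '", path, "' must be named 'gene_id'")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop_("duplicate gene ids in '", path, "' at line(s) ",
          paste(utils::head(which(duplicated(ids)) + 1L, 5L), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1L]))
    stop_("duplicate sample ids in '", path, "'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_("non-numeric expression values in '", path, "'")
  rownames(m) <- ids
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  expression_dataset(m, dataset_id, context)
}

#' Write a genes x samples expression TSV
#'
#' @param ds an [expression_dataset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene_id = gene_ids(ds), ds$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene ids.
#' Duplicate genes within a set are dropped with a warning.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop_("malformed GMT line ", i, " in '", path,
                              "': need name, description and >= 1 gene")
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in GMT set '", f[1L], "' (line ", i,
              ") de-duplicated", call. = FALSE)
      genes <- unique(genes)
    }
    sets[[f[1L]]] <- genes
    desc[f[1L]] <- f[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled; default the
#'   set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = names(sets)) {
  description <- rep(description, length.out = length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write module weight tables
#'
#' Long-format TSV with columns `module_id`, `gene_id`, `weight`.
#'
#' @param path file path.
#' @return `read_weights_tsv`: named list of `coex_module`-style weight
#'   vectors (named numeric vectors, one per module).
#' @export
read_weights_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("module_id", "gene_id", "weight")
  if (!all(need %in% colnames(df)))
    stop_("'", path, "' must have columns ", paste(need, collapse = ", "))
  lapply(split(df, df$module_id), function(d) {
    if (anyDuplicated(d$gene_id))
      stop_("duplicate gene ids for module '", d$module_id[1L], "'")
    stats::setNames(as.numeric(d$weight), d$gene_id)
  })
}

#' @rdname read_weights_tsv
#' @param modules named list of `coex_module` objects or named weight
#'   vectors.
#' @export
write_weights_tsv <- function(modules, path) {
  rows <- lapply(names(modules), function(mid) {
    m <- modules[[mid]]
    w <- if (inherits(m, "coex_module")) m$weights else m
    data.frame(module_id = mid, gene_id = names(w),
               weight = sprintf("%.12g", unname(w)),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clinical annotation TSV
#'
#' Columns `sample_id` and `dataset_id` are required; the standard optional
#' columns are `time`, `event`, `pcr`, `subtype`, `er_status`,
#' `her2_status`, `met_site`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "dataset_id") %in% colnames(df)))
    stop_("'", path, "' must have sample_id and dataset_id columns")
  if (anyDuplicated(df$sample_id))
    stop_("duplicate sample ids in '", path, "'")
  df
}

#' Read a dataset manifest TSV
#'
#' Columns: `dataset_id`, `path` (expression TSV, relative paths resolved
#' against the manifest's directory), `context`.
#'
#' @param path manifest path.
#' @return list of [expression_dataset]s.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("dataset_id", "path", "context")
  if (!all(need %in% colnames(df)))
    stop_("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, df$path[i])
    read_expression_tsv(p, dataset_id = df$dataset_id[i],
                        context = df$context[i])
  })
}
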
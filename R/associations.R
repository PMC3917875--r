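#' Within-module gene-gene coherence in one dataset
#'
#' Computes all-pairs Pearson correlations between the module's genes on the
#' z-scored data, their Fisher z-transforms (r clipped to +/-(1 - 1e-12)),
#' and the variance of the module score — the quantities used to compare
#' tumor-context and cell-line-context coherence.
#'
#' @param module a `coex_module` (or named weight vector / character vector
#'   of gene ids).
#' @param ds a z-scored [expression_dataset] containing >= 2 module genes.
#' @return list of class `coherence_record`: `module_id`, `context`,
#'   `pairwise_r`, `fisher_z`, `mean_fisher_z`, `mean_r_back` (tanh of the
#'   mean z), `median_r`, `score_variance`, `n_genes`.
#' @export
coherence_stats <- function(module, ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  genes <- if (inherits(module, "coex_module")) module$gene_ids
           else if (is.character(module)) module else names(module)
  mid <- if (inherits(module, "coex_module")) module$module_id else "module"
  present <- intersect(genes, gene_ids(ds))
  if (length(present) < 2L)
    stop_("fewer than 2 module genes present in '", ds$dataset_id, "'")
  C <- stats::cor(t(ds$values[present, , drop = FALSE]))
  r <- C[upper.tri(C)]
  z <- atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
  sv <- if (inherits(module, "coex_module"))
    stats::var(score_module(module, ds)) else
    stats::var(drop(colMeans(ds$values[present, , drop = FALSE])))
  structure(list(module_id = mid, context = ds$context, pairwise_r = r,
                 fisher_z = z, mean_fisher_z = mean(z),
                 mean_r_back = tanh(mean(z)), median_r = stats::median(r),
                 score_variance = sv, n_genes = length(present)),
            class = "coherence_record")
}

#' Compare module coherence between two contexts
#'
#' Welch two-sample t-test on the Fisher-transformed gene-pair correlations
#' of the two records (e.g. tumor vs cell line); the estimate is the mean
#' difference `a - b` on the z scale.
#'
#' @param a,b `coherence_record`s for the same module.
#' @return one-row data.frame: `module_id`, `model = "ttest"`, `estimate`,
#'   `p`.
#' @export
compare_coherence <- function(a, b) {
  stopifnot(inherits(a, "coherence_record"), inherits(b, "coherence_record"))
  if (length(a$fisher_z) < 2L || length(b$fisher_z) < 2L)
    stop_("need at least 2 gene pairs on each side")
  tt <- stats::t.test(a$fisher_z, b$fisher_z)
  data.frame(module_id = a$module_id, model = "ttest",
             estimate = unname(tt$estimate[1] - tt$estimate[2]),
             p = tt$p.value, stringsAsFactors = FALSE)
}

#' F-test comparing module score variances between two datasets
#'
#' @param module a `coex_module`.
#' @param a,b z-scored [expression_dataset]s (>= 3 samples each).
#' @return one-row data.frame: `module_id`, `model = "ftest"`, `estimate`
#'   (the F ratio `var_a / var_b`), `p` (two-sided).
#' @export
compare_score_variance <- function(module, a, b) {
  if (ncol(a$values) < 3L || ncol(b$values) < 3L)
    stop_("need at least 3 samples in each dataset")
  sa <- score_module(module, a); sb <- score_module(module, b)
  if (stats::var(sb) == 0) stop_("zero score variance in '", b$dataset_id, "'")
  vt <- stats::var.test(sa, sb)
  data.frame(module_id = module$module_id, model = "ftest",
             estimate = unname(vt$estimate), p = vt$p.value,
             stringsAsFactors = FALSE)
}

#' Classify a module as tumor-intrinsic or microenvironment-extrinsic
#'
#' Extrinsic: member genes are uncorrelated in cell lines (mean
#' back-transformed r < 0.1) yet correlated in tumors (median r > 0.35) —
#' the coherence comes from the microenvironment, which cell lines lack.
#' Intrinsic: median r > 0.35 in both contexts. Anything else is
#' indeterminate.
#'
#' @param tumor `coherence_record` from a tumor-context dataset.
#' @param cellline `coherence_record` from a cell-line-context dataset.
#' @return `"intrinsic"`, `"extrinsic"` or `"indeterminate"`.
#' @export
classify_intrinsic_extrinsic <- function(tumor, cellline) {
  stopifnot(inherits(tumor, "coherence_record"),
            inherits(cellline, "coherence_record"))
  if (cellline$mean_r_back < 0.1 && tumor$median_r > 0.35) return("extrinsic")
  if (tumor$median_r > 0.35 && cellline$median_r > 0.35) return("intrinsic")
  "indeterminate"
}

#' ROC AUC with the Youden-optimal threshold
#'
#' AUC by the rank (Mann-Whitney) formula with ties counted 1/2. The Youden
#' threshold maximizes sensitivity + specificity - 1 over the observed score
#' cut-points (classify positive when score >= cut-point; ties in the Youden
#' index are broken toward higher specificity).
#'
#' @param scores numeric vector.
#' @param label binary vector (0/1 or logical), both classes present.
#' @return list of class `auc_record`: `auc`, `youden_threshold`,
#'   `sensitivity`, `specificity`.
#' @export
subtype_auc <- function(scores, label) {
  label <- as.integer(as.logical(label))
  if (length(scores) != length(label)) stop_("length mismatch")
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop_("both classes must be nonempty")
  r <- rank(scores)  # midranks handle ties as 1/2 wins
  auc <- (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(scores))
  best <- NULL
  for (t in cuts) {
    pred <- scores >= t
    sens <- sum(pred & label == 1L) / n1
    spec <- sum(!pred & label == 0L) / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec))
      best <- list(t = t, sens = sens, spec = spec, j = j)
  }
  structure(list(auc = auc, youden_threshold = best$t,
                 sensitivity = best$sens, specificity = best$spec),
            class = "auc_record")
}

#' Published-signature scoring of a dataset
#'
#' Two signature types are supported: `weighted_mean` signatures score a
#' sample as the mean of its z-scored expression over the signature genes
#' weighted +1/-1 by direction of association; `centroid` signatures score a
#' sample as the Pearson correlation between its expression over the
#' signature genes and the published centroid.
#'
#' @param ds a z-scored [expression_dataset].
#' @param sig list with `name`, `type` (`"weighted_mean"` or `"centroid"`)
#'   and either `gene_weights` (named +1/-1 vector) or `centroid` (named
#'   numeric vector).
#' @return named per-sample numeric vector.
#' @export
signature_score <- function(ds, sig) {
  stopifnot(inherits(ds, "expression_dataset"))
  type <- match.arg(sig$type, c("weighted_mean", "centroid"))
  w <- if (type == "weighted_mean") sig$gene_weights else sig$centroid
  present <- intersect(names(w), gene_ids(ds))
  if (length(present) == 0L)
    stop_("no signature gene present in '", ds$dataset_id, "'")
  v <- ds$values[present, , drop = FALSE]
  if (type == "weighted_mean") {
    drop(crossprod(v, w[present])) / length(present)
  } else {
    if (length(present) < 3L) stop_("centroid scoring needs >= 3 genes")
    apply(v, 2L, function(col) stats::cor(col, w[present]))
  }
}

#' Pearson correlation between module and signature scores
#'
#' @param mscores,sscores equal-length numeric vectors (n >= 3, nonzero
#'   variance).
#' @return Pearson r.
#' @export
module_signature_correlation <- function(mscores, sscores) {
  if (length(mscores) != length(sscores) || length(mscores) < 3L)
    stop_("need equal-length vectors of length >= 3")
  if (stats::sd(mscores) == 0 || stats::sd(sscores) == 0)
    stop_("zero-variance input")
  stats::cor(mscores, sscores)
}

#' Dichotomize module scores
#'
#' `"median"` flags samples with score strictly above the median;
#' `"lower_tertile"` flags samples at or below the 33.33rd percentile
#' (linear-interpolation quantile). The flagged group is coded 1.
#'
#' @param scores numeric vector (n >= 3).
#' @param rule `"median"` or `"lower_tertile"`.
#' @return integer 0/1 vector.
#' @export
dichotomize <- function(scores, rule = c("median", "lower_tertile")) {
  rule <- match.arg(rule)
  if (length(scores) < 3L) stop_("need at least 3 scores")
  switch(rule,
         median = as.integer(scores > stats::median(scores)),
         lower_tertile = as.integer(scores <=
                                      stats::quantile(scores, 1 / 3,
                                                      names = FALSE)))
}

as_score_table <- function(scores) {
  s <- as.matrix(scores)
  if (is.null(colnames(s))) colnames(s) <- paste0("module", seq_len(ncol(s)))
  s
}

#' Cox proportional-hazards association of module scores with survival
#'
#' One proportional-hazards fit per module (partial likelihood, Efron ties),
#' optionally adjusted for covariates; the estimate is the log hazard ratio
#' per unit score with its Wald p-value, and q-values are BH-adjusted across
#' modules. Non-convergent fits are flagged (`converged = FALSE`), not
#' silently dropped.
#'
#' @param scores samples x modules matrix (or vector for one module).
#' @param time,event survival time (nonnegative) and event indicator (0/1;
#'   >= 10 events required).
#' @param covariates optional data.frame of adjustment columns.
#' @return data.frame: `module_id`, `model = "cox"`, `estimate` (log-HR),
#'   `se`, `p`, `q`, `converged`, `covariates`.
#' @export
cox_association <- function(scores, time, event, covariates = NULL) {
  s <- as_score_table(scores)
  if (any(time < 0)) stop_("negative survival times")
  if (sum(event) < 10L) stop_("need at least 10 events")
  cov_label <- if (is.null(covariates)) "" else
    paste(colnames(covariates), collapse = "+")
  rows <- lapply(colnames(s), function(mid) {
    x <- s[, mid]
    if (stats::sd(x) == 0) stop_("zero-variance score column '", mid, "'")
    df <- data.frame(time = time, event = event, score = x)
    if (!is.null(covariates)) df <- cbind(df, covariates)
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ ., data = df,
                      ties = "efron"),
      warning = function(w) {
        f <- suppressWarnings(survival::coxph(
          survival::Surv(time, event) ~ ., data = df, ties = "efron"))
        attr(f, "flagged") <- TRUE
        f
      })
    sm <- summary(fit)$coefficients
    conv <- is.null(attr(fit, "flagged")) && all(is.finite(sm["score", ]))
    data.frame(module_id = mid, model = "cox",
               estimate = sm["score", "coef"], se = sm["score", "se(coef)"],
               p = sm["score", "Pr(>|z|)"], converged = conv,
               covariates = cov_label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[, c("module_id", "model", "estimate", "se", "p", "q", "converged",
          "covariates")]
}

#' Logistic association of module scores with a binary response
#'
#' One maximum-likelihood logistic fit per module (optionally adjusted for
#' covariates): log odds ratio, Wald p, BH q across modules, and the
#' in-sample AUC of the fitted probabilities. Perfect separation is flagged.
#'
#' @param scores samples x modules matrix (or vector).
#' @param outcome binary vector; both classes need >= 5 samples.
#' @param covariates optional data.frame of adjustment columns.
#' @return data.frame: `module_id`, `model = "logistic"`, `estimate`
#'   (log-OR), `se`, `p`, `q`, `auc`, `converged`, `covariates`.
#' @export
logistic_response <- function(scores, outcome, covariates = NULL) {
  s <- as_score_table(scores)
  outcome <- as.integer(as.logical(outcome))
  if (min(table(factor(outcome, levels = 0:1))) < 5L)
    stop_("each outcome class needs at least 5 samples")
  cov_label <- if (is.null(covariates)) "" else
    paste(colnames(covariates), collapse = "+")
  rows <- lapply(colnames(s), function(mid) {
    df <- data.frame(outcome = outcome, score = s[, mid])
    if (!is.null(covariates)) df <- cbind(df, covariates)
    flagged <- FALSE
    fit <- withCallingHandlers(
      stats::glm(outcome ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (flagged)
      warning("possible separation or non-convergence for module '", mid, "'",
              call. = FALSE)
    sm <- summary(fit)$coefficients
    auc <- subtype_auc(stats::fitted(fit), outcome)$auc
    data.frame(module_id = mid, model = "logistic",
               estimate = sm["score", "Estimate"],
               se = sm["score", "Std. Error"],
               p = sm["score", "Pr(>|z|)"], auc = auc,
               converged = fit$converged && !flagged,
               covariates = cov_label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[, c("module_id", "model", "estimate", "se", "p", "q", "auc",
          "converged", "covariates")]
}

#' Welch t-test for a module score difference between two groups
#'
#' @param scores numeric vector.
#' @param groups binary vector (both groups >= 3 samples).
#' @param module_id label for the output row.
#' @return one-row data.frame: `module_id`, `model = "ttest"`, `estimate`
#'   (mean group-1 minus mean group-0), `p`.
#' @export
group_mean_difference <- function(scores, groups, module_id = "module") {
  groups <- as.integer(as.logical(groups))
  if (min(table(factor(groups, levels = 0:1))) < 3L)
    stop_("each group needs at least 3 samples")
  tt <- stats::t.test(scores[groups == 1L], scores[groups == 0L])
  data.frame(module_id = module_id, model = "ttest",
             estimate = unname(tt$estimate[1] - tt$estimate[2]),
             p = tt$p.value, stringsAsFactors = FALSE)
}

#' Pool datasets on a shared gene universe
#'
#' Mean-centers every gene within each dataset, then concatenates samples.
#' Per-source centering removes dataset-level location differences so pooled
#' projections are comparable across sources; the dataset of origin is kept
#' as per-sample metadata (attribute `source` and `dataset:sample` column
#' names).
#'
#' @param datasets list of [expression_dataset]s with identical gene ids.
#' @return a pooled [expression_dataset] (context `"mixed"` unless all
#'   sources share one context).
#' @export
pool_datasets <- function(datasets) {
  if (length(datasets) < 1L) stop_("need at least one dataset")
  universe <- gene_ids(datasets[[1]])
  for (d in datasets)
    if (!identical(gene_ids(d), universe))
      stop_("gene universe mismatch in '", d$dataset_id,
            "'; run restrict_to_common_genes() first")
  mats <- lapply(datasets, function(d) {
    m <- d$values - rowMeans(d$values)
    colnames(m) <- paste(d$dataset_id, colnames(m), sep = ":")
    m
  })
  ctx <- unique(vapply(datasets, `[[`, character(1), "context"))
  pooled <- expression_dataset(do.call(cbind, mats),
                               dataset_id = "pooled",
                               context = if (length(ctx) == 1L) ctx else "mixed")
  attr(pooled, "source") <- rep(vapply(datasets, `[[`, character(1),
                                       "dataset_id"),
                                vapply(datasets, function(d) ncol(d$values),
                                       integer(1)))
  pooled
}
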
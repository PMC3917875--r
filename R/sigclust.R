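#' Cluster index of a two-group partition
#'
#' `CI = (within-cluster sum of squared distances to the two cluster means) /
#' (total sum of squared distances to the overall mean)`. Values near 0
#' indicate a crisp two-group structure; values near 1 indicate no structure
#' beyond a single cloud.
#'
#' @param data numeric matrix, observations in rows.
#' @param labels vector with exactly two distinct values, both present.
#' @return scalar in [0, 1].
#' @export
cluster_index <- function(data, labels) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop_("need at least 2 observations")
  if (length(labels) != nrow(data)) stop_("labels length must match rows")
  lv <- unique(labels)
  if (length(lv) != 2L) stop_("labels must have exactly two classes")
  center <- colMeans(data)
  tss <- sum(sweep(data, 2L, center, "-")^2)
  if (tss == 0) stop_("total sum of squares is zero (all points identical)")
  wss <- 0
  for (l in lv) {
    sub <- data[labels == l, , drop = FALSE]
    wss <- wss + sum(sweep(sub, 2L, colMeans(sub), "-")^2)
  }
  wss / tss
}

#' Estimate the null covariance eigenvalues for SigClust
#'
#' The null hypothesis is a single multivariate Gaussian. Its background
#' noise variance is estimated robustly as `sigma_n2 = (MAD of the
#' feature-centered data entries / qnorm(0.75))^2`, and the sample covariance
#' eigenvalues `lambda_j` are then thresholded against it:
#' * `hard`: `lambda~_j = max(lambda_j, sigma_n2)`;
#' * `soft`: `lambda~_j = max(lambda_j - tau, sigma_n2)` with the shift
#'   `tau >= 0` chosen so that the total variance is preserved
#'   (`sum(lambda~) = sum(lambda)`) whenever that is feasible, and `tau = 0`
#'   otherwise. Soft thresholding removes the upward bias of the leading
#'   sample eigenvalues instead of only flooring the small ones.
#'
#' @param data numeric matrix (>= 3 observations, >= 1 feature).
#' @param method `"hard"` or `"soft"`.
#' @return list with `sigma_n2` and `eigenvalues` (all >= `sigma_n2`).
#' @export
estimate_null_eigenvalues <- function(data, method = c("hard", "soft")) {
  method <- match.arg(method)
  data <- as.matrix(data)
  if (nrow(data) < 3L) stop_("need at least 3 observations")
  centered <- sweep(data, 2L, colMeans(data), "-")
  s <- stats::mad(as.vector(centered))  # constant 1/qnorm(0.75) is mad()'s default
  if (s == 0) stop_("degenerate data: MAD of centered entries is zero")
  sigma_n2 <- s^2
  ev <- eigen(stats::cov(data), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  lam <- switch(method,
    hard = pmax(ev, sigma_n2),
    soft = {
      target <- sum(ev)
      f <- function(tau) sum(pmax(ev - tau, sigma_n2)) - target
      if (f(0) <= 0) {
        pmax(ev, sigma_n2)  # tau = 0 already at (or below) the target
      } else if (f(max(ev)) >= 0) {
        # even full shrinkage stays above the target (sigma_n2 exceeds the
        # mean eigenvalue): the floor is binding everywhere
        rep(sigma_n2, length(ev))
      } else {
        tau <- stats::uniroot(f, c(0, max(ev)), tol = 1e-10)$root
        pmax(ev - tau, sigma_n2)
      }
    })
  list(sigma_n2 = sigma_n2, eigenvalues = lam)
}

#' SigClust: significance of a 2-way partition
#'
#' Tests whether the observed two-group cluster index could arise from a
#' single multivariate Gaussian. `n_sims` null datasets of the same shape are
#' drawn from a zero-mean Gaussian with diagonal covariance `diag(lambda~)`
#' (simulation in the eigenbasis is exact because the cluster index is
#' rotation invariant); each is partitioned by 2-means (best of 10 seeded
#' restarts) and its CI recorded. The empirical p-value is
#' `(1 + #\{null CI <= observed CI\}) / (n_sims + 1)`.
#'
#' @param data numeric matrix, observations in rows.
#' @param labels two-class labels of the observed partition; if `NULL`, the
#'   observed partition is itself obtained by 2-means with 10 restarts.
#' @param method eigenvalue thresholding, `"hard"` or `"soft"`.
#' @param n_sims number of null simulations (>= 100; default 1000).
#' @param seed integer seed.
#' @return list of class `sigclust_result`: `ci_observed`, `null_ci`,
#'   `p_value`, `method`, `n_sims`, `seed`, `sigma_n2`, `null_eigenvalues`.
#' @export
sigclust_pvalue <- function(data, labels = NULL, method = c("hard", "soft"),
                            n_sims = 1000L, seed = 0L) {
  method <- match.arg(method)
  if (!is_count(n_sims, 100L)) stop_("n_sims must be an integer >= 100")
  data <- as.matrix(data)
  n <- nrow(data); d <- ncol(data)
  if (is.null(labels)) {
    labels <- with_seed(derive_seed(seed, "sigclust_obs"),
                        stats::kmeans(data, 2L, nstart = 10L)$cluster)
  }
  ci_obs <- cluster_index(data, labels)
  est <- estimate_null_eigenvalues(data, method)
  sds <- sqrt(est$eigenvalues[seq_len(min(d, length(est$eigenvalues)))])
  if (length(sds) < d) sds <- c(sds, rep(sqrt(est$sigma_n2), d - length(sds)))
  null_ci <- with_seed(derive_seed(seed, "sigclust_null", method), {
    vapply(seq_len(n_sims), function(i) {
      sim <- matrix(stats::rnorm(n * d), n, d) %*% diag(sds, d)
      km <- stats::kmeans(sim, 2L, nstart = 10L)
      cluster_index(sim, km$cluster)
    }, numeric(1))
  })
  structure(list(ci_observed = ci_obs, null_ci = null_ci,
                 p_value = (1 + sum(null_ci <= ci_obs)) / (n_sims + 1),
                 method = method, n_sims = as.integer(n_sims),
                 seed = as.integer(seed), sigma_n2 = est$sigma_n2,
                 null_eigenvalues = est$eigenvalues),
            class = "sigclust_result")
}

#' @export
print.sigclust_result <- function(x, ...) {
  cat(sprintf("<sigclust> CI = %.4f, p = %.4g (%s thresholding, %d sims)\n",
              x$ci_observed, x$p_value, x$method, x$n_sims))
  invisible(x)
}

#' Pairwise SigClust tests between consensus modules
#'
#' For every unordered pair of modules, the observations are the member
#' clusters' rows of the score-correlation matrix (the same feature space
#' used to define the modules) and the labels are the module assignment
#' itself: the test asks whether the assigned two-module split of those
#' clusters is distinct. Modules with fewer than 2 member clusters are
#' skipped with a warning.
#'
#' @param assignment named map cluster id -> module id (see
#'   [define_modules()]).
#' @param corr score-correlation matrix over (at least) the assigned
#'   clusters.
#' @param method `"hard"` or `"soft"`.
#' @param n_sims,seed forwarded to [sigclust_pvalue()].
#' @return data.frame with columns `module_a`, `module_b`, `ci`, `p_value`,
#'   `method`; attribute `results` holds the full `sigclust_result` objects.
#' @export
pairwise_module_sigclust <- function(assignment, corr,
                                     method = c("hard", "soft"),
                                     n_sims = 1000L, seed = 0L) {
  method <- match.arg(method)
  mods <- sort(unique(assignment))
  if (length(mods) < 2L) stop_("need at least 2 modules")
  sizes <- table(assignment)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("module(s) with a single member cluster skipped: ",
            paste(small, collapse = ", "), call. = FALSE)
    mods <- setdiff(mods, small)
  }
  rows <- list(); full <- list()
  for (i in seq_along(mods)) for (j in seq_len(i - 1L)) {
    a <- mods[[j]]; b <- mods[[i]]
    cids <- names(assignment)[assignment %in% c(a, b)]
    res <- sigclust_pvalue(corr[cids, , drop = FALSE],
                           labels = assignment[cids], method = method,
                           n_sims = n_sims,
                           seed = derive_seed(seed, "pair", a, b))
    rows[[length(rows) + 1L]] <- data.frame(module_a = a, module_b = b,
                                            ci = res$ci_observed,
                                            p_value = res$p_value,
                                            method = method,
                                            stringsAsFactors = FALSE)
    full[[paste(a, b, sep = ":")]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- full
  out
}
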
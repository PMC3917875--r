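test_that("coherence statistics use Fisher-transformed all-pairs correlation", {
  set.seed(81)
  lat <- rbinom(80, 1, 0.5)
  m <- 3 * matrix(lat, 10, 80, byrow = TRUE) + matrix(rnorm(800), 10, 80)
  dimnames(m) <- list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:80))
  ds <- zscore_genes(expression_dataset(m, "t", context = "tumor"))
  rec <- coherence_stats(sprintf("g%02d", 1:10), ds)
  expect_length(rec$pairwise_r, choose(10, 2))
  expect_gt(rec$median_r, 0.35)
  expect_equal(rec$fisher_z, atanh(rec$pairwise_r), tolerance = 1e-9)
  expect_equal(rec$mean_r_back, tanh(mean(rec$fisher_z)))
  # closed-form checks of the transform itself
  expect_equal(atanh(0), 0)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_error(coherence_stats("g01", ds), "fewer than 2")
})

test_that("coherence comparison is a symmetric Welch t-test on z vectors", {
  a <- structure(list(module_id = "M1", fisher_z = c(0.5, 0.6, 0.7, 0.4)),
                 class = "coherence_record")
  b <- structure(list(module_id = "M1", fisher_z = c(0.1, 0.0, 0.2, 0.1)),
                 class = "coherence_record")
  ab <- compare_coherence(a, b)
  ba <- compare_coherence(b, a)
  expect_equal(ab$estimate, mean(a$fisher_z) - mean(b$fisher_z))
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$p, ba$p)
  same <- compare_coherence(a, a)
  expect_equal(same$estimate, 0)
  expect_equal(same$p, 1)
})

test_that("score variance F-test matches the F distribution and is symmetric", {
  set.seed(82)
  mk <- function(sd, id) {
    m <- matrix(rnorm(2 * 50), 2, 50, dimnames = list(c("gA", "gB"),
                                                      sprintf("s%02d", 1:50)))
    # module score variance controlled through one gene's scale
    m[1, ] <- m[1, ] * sd
    expression_dataset(m, id)
  }
  mod <- structure(list(module_id = "M", gene_ids = "gA",
                        weights = c(gA = 1), contributing_datasets = "a"),
                   class = "coex_module")
  a <- mk(2, "a"); b <- mk(1, "b")
  ab <- compare_score_variance(mod, a, b)
  ba <- compare_score_variance(mod, b, a)
  expect_equal(ab$estimate, 1 / ba$estimate, tolerance = 1e-10)
  expect_equal(ab$p, ba$p, tolerance = 1e-10)
  expect_lt(ab$p, 1e-3)  # var ratio ~4 at n=50 each
  self <- compare_score_variance(mod, a, a)
  expect_equal(self$estimate, 1)
  expect_equal(self$p, 1)
})

test_that("intrinsic/extrinsic rule follows the coherence thresholds", {
  rec <- function(med, back) structure(list(median_r = med,
                                            mean_r_back = back),
                                       class = "coherence_record")
  expect_equal(classify_intrinsic_extrinsic(rec(0.6, 0.6), rec(0.05, 0.05)),
               "extrinsic")
  expect_equal(classify_intrinsic_extrinsic(rec(0.6, 0.6), rec(0.6, 0.6)),
               "intrinsic")
  expect_equal(classify_intrinsic_extrinsic(rec(0.2, 0.2), rec(0.05, 0.05)),
               "indeterminate")
})

test_that("AUC equals all-pairs counting and Youden picks the optimal cut", {
  r <- subtype_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # tie case: pairs (3>2), (3>1), (1<2), (1=1 -> 1/2) = 2.5/4
  expect_equal(subtype_auc(c(2, 1, 3, 1), c(0, 0, 1, 1))$auc, 0.625)
  expect_error(subtype_auc(1:4, c(1, 1, 1, 1)), "nonempty")
  # brute-force all-pairs oracle
  set.seed(83)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    sc <- sample(1:8, n, replace = TRUE)  # heavy ties
    lb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    pos <- sc[lb == 1]; neg <- sc[lb == 0]
    wins <- 0
    for (p in pos) for (q in neg)
      wins <- wins + (p > q) + 0.5 * (p == q)
    expect_equal(subtype_auc(sc, lb)$auc, wins / (length(pos) * length(neg)),
                 tolerance = 1e-12)
    # Youden threshold is optimal over all cuts
    got <- subtype_auc(sc, lb)
    js <- vapply(sort(unique(sc)), function(t)
      mean(sc[lb == 1] >= t) + mean(sc[lb == 0] < t) - 1, numeric(1))
    expect_equal(got$sensitivity + got$specificity - 1, max(js),
                 tolerance = 1e-12)
  }
  # labels independent of scores: AUC near 1/2
  set.seed(84)
  expect_lt(abs(subtype_auc(rnorm(2000),
                            rbinom(2000, 1, 0.5))$auc - 0.5), 0.04)
})

test_that("signature scoring handles weighted-mean and centroid types", {
  z <- matrix(c(1, 1, -1, 2), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  ds <- expression_dataset(z, "t")
  sig <- list(name = "w", type = "weighted_mean",
              gene_weights = c(gA = 1, gB = -1))
  expect_equal(unname(signature_score(ds, sig)), c(0, -1.5))
  allplus <- list(name = "p", type = "weighted_mean",
                  gene_weights = c(gA = 1, gB = 1))
  expect_equal(unname(signature_score(ds, allplus)),
               unname(colMeans(z)))
  # centroid equal to the sample's own profile scores r = 1
  z3 <- matrix(rnorm(9), 3, 3, dimnames = list(paste0("g", 1:3),
                                               paste0("s", 1:3)))
  cent <- list(name = "c", type = "centroid",
               centroid = setNames(z3[, 1], rownames(z3)))
  expect_equal(unname(signature_score(expression_dataset(z3, "c"), cent))[1],
               1)
  expect_error(signature_score(ds, list(name = "x", type = "weighted_mean",
                                        gene_weights = c(gX = 1))),
               "no signature gene")
})

test_that("module-signature correlation is plain Pearson with guards", {
  x <- c(1.2, -0.5, 3.1, 0.4, 2.2)
  y <- c(0.8, -1.0, 2.5, 0.1, 1.4)
  expect_equal(module_signature_correlation(x, y), cor(x, y))
  expect_equal(module_signature_correlation(x, x), 1)
  expect_equal(module_signature_correlation(x, -x), -1)
  expect_error(module_signature_correlation(x, rep(1, 5)), "zero-variance")
  expect_error(module_signature_correlation(1:2, 1:2), "length >= 3")
})

test_that("dichotomization rules are strict and interpolated", {
  expect_equal(dichotomize(c(1, 2, 3, 4), "median"), c(0L, 0L, 1L, 1L))
  expect_equal(dichotomize(rep(2, 5), "median"), rep(0L, 5))
  expect_equal(dichotomize(1:9, "lower_tertile"),
               c(1L, 1L, 1L, rep(0L, 6)))
})

test_that("Cox association recovers a planted log hazard ratio", {
  set.seed(85)
  n <- 600
  s <- cbind(active = rbinom(n, 1, 0.5), noise = rnorm(n))
  h <- 0.1 * exp(0.7 * s[, "active"])
  t_ev <- rexp(n, h); t_c <- rexp(n, 0.05)
  tab <- cox_association(s, pmin(t_ev, t_c), as.integer(t_ev <= t_c))
  est <- tab$estimate[tab$module_id == "active"]
  expect_lt(abs(est - 0.7), 0.2)
  expect_lt(tab$q[tab$module_id == "active"], 0.05)
  expect_gt(tab$p[tab$module_id == "noise"], 0.001)
  expect_true(all(tab$q >= tab$p))
  expect_error(cox_association(s, pmin(t_ev, t_c), rep(0L, n)),
               "at least 10 events")
  expect_error(cox_association(cbind(flat = rep(1, n)), t_ev, rep(1L, n)),
               "zero-variance")
})

test_that("logistic association recovers sign and flags degenerate outcomes", {
  set.seed(86)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 1.0 * x))
  tab <- logistic_response(cbind(m1 = x), y)
  expect_gt(tab$estimate, 0.5)
  expect_lt(tab$q, 0.05)
  expect_gt(tab$auc, 0.6)
  # independent outcome: no signal
  tab0 <- logistic_response(cbind(m1 = x), rbinom(n, 1, 0.3))
  expect_lt(abs(tab0$estimate), 0.5)
  expect_error(logistic_response(cbind(m1 = x), rep(1L, n)), "at least 5")
  # perfect separation flagged, not silent
  ysep <- as.integer(x > 0)
  expect_warning(tsep <- logistic_response(cbind(m1 = x), ysep),
                 "separation")
  expect_false(tsep$converged)
})

test_that("group mean difference is a Welch test with sign symmetry", {
  set.seed(87)
  sc <- c(rnorm(30), rnorm(30, 2))
  gr <- rep(c(0, 1), each = 30)
  a <- group_mean_difference(sc, gr)
  b <- group_mean_difference(sc, 1 - gr)
  expect_lt(a$p, 1e-5)
  expect_equal(a$estimate, -b$estimate)
  expect_error(group_mean_difference(sc, c(rep(0, 58), 1, 1)), "at least 3")
})

test_that("pooling mean-centers per source and keeps origins", {
  d1 <- random_dataset(8, 10, seed = 88, dataset_id = "a")
  d2 <- random_dataset(8, 12, seed = 89, dataset_id = "b")
  d2$values <- d2$values + 5  # dataset-level shift
  pooled <- pool_datasets(list(d1, d2))
  expect_equal(ncol(pooled$values), 22)
  src <- attr(pooled, "source")
  for (g in rownames(pooled$values)) {
    expect_equal(mean(pooled$values[g, src == "a"]), 0, tolerance = 1e-12)
    expect_equal(mean(pooled$values[g, src == "b"]), 0, tolerance = 1e-12)
  }
  one <- pool_datasets(list(d1))
  expect_equal(unname(one$values),
               unname(d1$values - rowMeans(d1$values)))
  d3 <- random_dataset(5, 10, seed = 90, dataset_id = "c")
  expect_error(pool_datasets(list(d1, d3)), "mismatch")
})
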
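test_that("score correlations match hand-computed Pearson values", {
  m <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                1, 1, 2, 5), 3, 4, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), paste0("s", 1:4)))
  r <- cluster_score_correlations(m)
  expect_equal(diag(r), setNames(rep(1, 3), rownames(m)))
  expect_lt(max(abs(r - t(r))), 1e-12)
  expect_equal(r["c1", "c2"], cor(m[1, ], m[2, ]), tolerance = 1e-10)
  expect_equal(r["c1", "c3"],
               sum((m[1, ] - 2.5) * (m[3, ] - 2.25)) /
                 (sqrt(sum((m[1, ] - 2.5)^2)) *
                  sqrt(sum((m[3, ] - 2.25)^2))), tolerance = 1e-10)
  # identical rows correlate at exactly 1
  m2 <- rbind(m, c4 = m["c1", ])
  expect_equal(cluster_score_correlations(m2)["c1", "c4"], 1)
  m3 <- rbind(m, c4 = rep(2, 4))
  expect_error(cluster_score_correlations(m3), "c4")
  expect_error(cluster_score_correlations(m[1, , drop = FALSE]), "at least 2")
})

test_that("recurrence filter equals brute-force degree counting", {
  # 7-clique at r = 0.9: every member has exactly 6 neighbors
  r <- matrix(0.9, 7, 7); diag(r) <- 1
  dimnames(r) <- list(paste0("c", 1:7), paste0("c", 1:7))
  expect_setequal(filter_recurrent_clusters(r, consensus_params()),
                  paste0("c", 1:7))
  # 8th cluster linked only to c1 at 0.75: c1 gains a 7th neighbor, c8 dropped
  r8 <- matrix(0, 8, 8); r8[1:7, 1:7] <- 0.8; diag(r8) <- 1
  r8[1, 8] <- r8[8, 1] <- 0.75
  dimnames(r8) <- list(paste0("c", 1:8), paste0("c", 1:8))
  expect_setequal(filter_recurrent_clusters(r8, consensus_params()),
                  paste0("c", 1:7))
  # isolated cluster below threshold is dropped; strict inequality on r
  r2 <- matrix(0.7, 7, 7); diag(r2) <- 1  # exactly at the threshold
  dimnames(r2) <- list(paste0("c", 1:7), paste0("c", 1:7))
  expect_length(filter_recurrent_clusters(r2, consensus_params()), 0L)
  # brute-force oracle on random symmetric matrices
  set.seed(61)
  for (rep in 1:60) {
    n <- sample(3:30, 1)
    a <- matrix(runif(n * n, -1, 1), n, n)
    a <- (a + t(a)) / 2; diag(a) <- 1
    dimnames(a) <- list(paste0("k", 1:n), paste0("k", 1:n))
    pr <- consensus_params(r_threshold = runif(1, 0.2, 0.9),
                           min_neighbors = sample(1:6, 1))
    keep <- character(0)
    for (i in 1:n) {
      deg <- 0L
      for (j in 1:n) if (j != i && a[i, j] > pr$r_threshold) deg <- deg + 1L
      if (deg >= pr$min_neighbors) keep <- c(keep, rownames(a)[i])
    }
    expect_identical(filter_recurrent_clusters(a, pr), keep)
  }
})

test_that("module definition recovers block structure and is permutation-stable", {
  set.seed(62)
  # two blocks of clusters with high within- and negative between-correlation
  block <- function(n, r) {
    m <- matrix(r, n, n); diag(m) <- 1; m
  }
  corr <- rbind(cbind(block(5, 0.9), matrix(-0.2, 5, 4)),
                cbind(matrix(-0.2, 4, 5), block(4, 0.9)))
  corr <- corr + matrix(rnorm(81, 0, 0.01), 9, 9)
  corr <- (corr + t(corr)) / 2; diag(corr) <- 1
  dimnames(corr) <- list(paste0("c", 1:9), paste0("c", 1:9))
  asg <- define_modules(corr, consensus_params())
  expect_length(unique(asg), 2L)
  expect_length(unique(asg[1:5]), 1L)
  expect_length(unique(asg[6:9]), 1L)
  expect_equal(unname(asg[1]), "M1")  # larger module labeled first
  # permuting the clusters permutes only the labels
  perm <- sample(9)
  asg2 <- define_modules(corr[perm, perm], consensus_params())
  expect_true(all(table(asg[names(asg2)], asg2) %in%
                  c(0, as.vector(table(asg)))))
  # degenerate: all correlations identical -> fallback k = 2 with warning
  flat <- block(6, 0.5)
  dimnames(flat) <- list(paste0("c", 1:6), paste0("c", 1:6))
  expect_warning(asgf <- define_modules(flat, consensus_params()),
                 "degenerate")
  expect_length(unique(asgf), 2L)
  expect_error(define_modules(corr[1, 1, drop = FALSE]), "at least 2")
})

test_that("membership rule applies the strict >1/3 threshold", {
  mk_cl <- function(id, genes)
    structure(list(cluster_id = id, source_dataset_id = "d",
                   gene_ids = genes, metagene = NULL),
              class = "gene_cluster")
  cls <- list(mk_cl("c1", c("a", "b", "x")), mk_cl("c2", c("a", "b")),
              mk_cl("c3", c("a", "y")), mk_cl("c4", c("a", "b")),
              mk_cl("c5", c("a", "z")))
  asg <- setNames(rep("M1", 5), paste0("c", 1:5))
  gs <- module_gene_sets(asg, cls, consensus_params())
  # a in 5/5, b in 3/5 = 0.6 -> in; x,y,z in 1/5 = 0.2 -> out
  expect_identical(gs$M1, c("a", "b"))
  # 1 of 3 clusters is exactly 1/3: excluded under the strict rule
  asg3 <- setNames(rep("M1", 3), paste0("c", 1:3))
  gs3 <- module_gene_sets(asg3, cls[1:3], consensus_params())
  expect_false("y" %in% gs3$M1)  # y in 1/3 exactly
  expect_true("a" %in% gs3$M1)   # a in 3/3
  expect_true("b" %in% gs3$M1)   # b in 2/3
  # all-singleton membership errors with a diagnostic
  cls2 <- list(mk_cl("c1", "p"), mk_cl("c2", "q"), mk_cl("c3", "r"))
  expect_error(module_gene_sets(setNames(rep("M1", 3), paste0("c", 1:3)),
                                cls2, consensus_params()), "top gene")
})

test_that("module weights reduce to the cluster metagene for one cluster", {
  sim <- small_sim(seed = 31)
  comp <- suppressWarnings(preprocess_compendium(sim$compendium))
  memb <- sim$truth$gene_membership
  genes <- intersect(names(memb)[!is.na(memb) & memb == "modA"],
                     comp$gene_universe)
  cl <- structure(list(cluster_id = "SIM01.c01", source_dataset_id = "SIM01",
                       gene_ids = genes, metagene = NULL),
                  class = "gene_cluster")
  cl <- compute_metagene(cl, comp$datasets$SIM01)
  mod <- module_weights(genes, comp, contributing_datasets = "SIM01",
                        module_id = "M1")
  expect_equal(mod$weights[names(cl$metagene)], cl$metagene,
               tolerance = 1e-10)
  # two perfectly correlated genes across the pooled union
  base <- rnorm(30)
  m <- rbind(gA = base, gB = base)
  colnames(m) <- paste0("s", 1:30)
  cp <- compendium(list(expression_dataset(m, "p1")))
  w2 <- module_weights(c("gA", "gB"), cp)
  expect_equal(unname(w2$weights), c(sqrt(0.5), sqrt(0.5)))
  expect_warning(w1 <- module_weights("gA", cp), "single-gene")
  expect_equal(unname(w1$weights), 1)
  # recovered weights align with the planted loading direction
  lo <- sim$truth$loadings$modA[mod$gene_ids]
  cosine <- sum(mod$weights * lo) / sqrt(sum(lo^2))
  expect_gt(abs(cosine), 0.9)
})

test_that("module scoring reproduces pooled-PCA scores on contributors", {
  sim <- small_sim(seed = 37)
  comp <- suppressWarnings(preprocess_compendium(sim$compendium))
  memb <- sim$truth$gene_membership
  genes <- intersect(names(memb)[!is.na(memb) & memb == "modB"],
                     comp$gene_universe)
  mod <- module_weights(genes, comp,
                        contributing_datasets = c("SIM01", "SIM02"),
                        module_id = "MB")
  pooled <- do.call(cbind, lapply(comp$datasets[c("SIM01", "SIM02")],
                                  function(d) d$values[mod$gene_ids, ]))
  sv <- svd(pooled)
  pc_scores <- sv$d[1] * sv$v[, 1]
  got <- c(score_module(mod, comp$datasets$SIM01),
           score_module(mod, comp$datasets$SIM02))
  expect_lt(min(max(abs(got - pc_scores)), max(abs(got + pc_scores))), 1e-8)
  # one-hot weights score a single gene row
  onehot <- structure(list(module_id = "X", gene_ids = genes[1],
                           weights = setNames(1, genes[1]),
                           contributing_datasets = "SIM01"),
                      class = "coex_module")
  expect_equal(unname(score_module(onehot, comp$datasets$SIM01)),
               unname(comp$datasets$SIM01$values[genes[1], ]),
               ignore_attr = TRUE)
  # held-out dataset: score separates latent on/off samples
  s3 <- score_module(mod, comp$datasets$SIM03)
  lat <- sim$truth$latent_activity$SIM03["modB", names(s3)]
  expect_gt(subtype_auc(s3, lat)$auc, 0.95)
  ranks <- rank(s3)
  expect_lt(wilcox.test(s3[lat == 1], s3[lat == 0],
                        alternative = "greater")$p.value, 1e-6)
})
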
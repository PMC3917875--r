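test_that("gene intersection builds a sorted shared universe", {
  mk <- function(id, genes) {
    m <- matrix(seq_len(length(genes) * 3), length(genes), 3,
                dimnames = list(genes, paste0(id, "_", 1:3)))
    expression_dataset(m, id)
  }
  comp <- restrict_to_common_genes(list(mk("d1", c("C", "A", "B")),
                                        mk("d2", c("B", "D", "C"))))
  expect_identical(comp$gene_universe, c("B", "C"))
  expect_identical(rownames(comp$datasets$d1$values), c("B", "C"))
  # identical gene lists: universe unchanged up to sorting
  comp2 <- restrict_to_common_genes(list(mk("d1", c("b", "a")),
                                         mk("d2", c("b", "a"))))
  expect_identical(comp2$gene_universe, c("a", "b"))
  # pairwise-overlapping but jointly empty
  expect_error(restrict_to_common_genes(list(mk("d1", c("A", "B")),
                                             mk("d2", c("B", "C")),
                                             mk("d3", c("C", "A")))),
               "empty gene intersection")
  # order-insensitive up to dataset ordering
  a <- restrict_to_common_genes(list(mk("d1", c("C", "A", "B")),
                                     mk("d2", c("B", "D", "C"))))
  b <- restrict_to_common_genes(list(mk("d2", c("B", "D", "C")),
                                     mk("d1", c("C", "A", "B"))))
  expect_identical(a$gene_universe, b$gene_universe)
  expect_identical(a$datasets$d1$values, b$datasets$d1$values)
})

test_that("z-scoring gives mean-0, sd-1 rows and drops constant genes", {
  # hand case: the row (0, 2) standardizes to -1/sqrt(2), +1/sqrt(2)
  expect_equal(unname(coexmod:::zscore_rows(matrix(c(0, 2), 1, 2))[1, ]),
               c(-sqrt(0.5), sqrt(0.5)))
  ds <- random_dataset(10, 20, seed = 2)
  z <- zscore_genes(ds)
  expect_equal(unname(rowMeans(z$values)), rep(0, 10))
  expect_equal(unname(apply(z$values, 1, sd)), rep(1, 10))
  # idempotent on already standardized data
  z2 <- zscore_genes(z)
  expect_lt(max(abs(z2$values - z$values)), 1e-12)
  # constant gene dropped with a warning
  ds$values["g001", ] <- 5
  expect_warning(zc <- zscore_genes(ds), "zero-variance")
  expect_false("g001" %in% rownames(zc$values))
  # too few samples
  tiny <- expression_dataset(matrix(1:4, 2, 2,
                                    dimnames = list(c("a", "b"), c("x", "y"))),
                             "tiny")
  expect_error(zscore_genes(tiny), "fewer than 3 samples")
})

test_that("avg_z is the per-sample mean of gene z-scores", {
  ds <- zscore_genes(random_dataset(6, 12, seed = 3))
  ds <- compute_avg_z(ds)
  expect_equal(unname(ds$avg_z), unname(colMeans(ds$values)))
  # rows summing to zero at every sample give an all-zero avg_z
  m <- matrix(rnorm(15), 3, 5)
  m <- rbind(m, -m)  # antisymmetric pairs
  dimnames(m) <- list(paste0("g", 1:6), paste0("s", 1:5))
  d2 <- compute_avg_z(expression_dataset(m, "sym"))
  expect_equal(unname(d2$avg_z), rep(0, 5))
  # single-gene dataset: avg_z equals the gene row
  d3 <- compute_avg_z(expression_dataset(m[1, , drop = FALSE], "one"))
  expect_equal(unname(d3$avg_z), unname(m[1, ]))
})

test_that("quality adjustment residualizes on avg_z exactly", {
  # hand case: row (2,4,6) on avg_z (-1,0,1): slope 2, intercept 4, residual 0
  m <- matrix(c(2, 4, 6), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  ds <- expression_dataset(m, "h", avg_z = c(-1, 0, 1))
  adj <- quality_adjust(ds)
  expect_equal(unname(adj$values[1, ]), c(0, 0, 0))
  # a row equal to avg_z itself residualizes to zero
  ds2 <- expression_dataset(rbind(m, g2 = c(-1, 0, 1)), "h2",
                            avg_z = c(-1, 0, 1))
  expect_equal(unname(quality_adjust(ds2)$values["g2", ]), c(0, 0, 0))
  # mean-zero row orthogonal to avg_z is unchanged
  set.seed(4)
  z <- rnorm(20)
  row <- rnorm(20)
  row <- residuals(lm(row ~ z))  # orthogonal, mean 0
  d3 <- expression_dataset(matrix(row, 1, 20,
                                  dimnames = list("g", paste0("s", 1:20))),
                           "o", avg_z = z)
  expect_lt(max(abs(quality_adjust(d3)$values[1, ] - row)), 1e-10)
  # constant avg_z: skipped with warning
  d4 <- expression_dataset(m, "c", avg_z = c(1, 1, 1))
  expect_warning(out <- quality_adjust(d4), "constant")
  expect_identical(out$values, d4$values)
  expect_error(quality_adjust(expression_dataset(m, "n")), "avg_z")
})

test_that("quality adjustment is idempotent and kills gene-quality correlation", {
  sim <- small_sim(seed = 17, n_samples = 80)
  raw <- sim$compendium$datasets[[1]]
  z <- compute_avg_z(zscore_genes(raw))
  pre <- mean(abs(apply(z$values, 1, cor, y = z$avg_z)))
  expect_gt(pre, 0.2)  # quality_sd > 0 induces real confounding
  adj <- quality_adjust(z)
  post <- max(abs(apply(adj$values, 1, cor, y = adj$avg_z)))
  expect_lt(post, 1e-8)
  adj2 <- quality_adjust(adj)
  expect_lt(max(abs(adj2$values - adj$values)), 1e-10)
  # full chain: rows unit variance again, correlation still dead
  pp <- preprocess_dataset(raw)
  expect_equal(unname(apply(pp$values, 1, sd)), rep(1, nrow(pp$values)))
  expect_lt(max(abs(apply(pp$values, 1, cor, y = pp$avg_z))), 1e-8)
})
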
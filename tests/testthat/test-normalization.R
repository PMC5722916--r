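test_that("TPM normalization matches hand computation and conserves 1e6", {
  ann <- gene_annotation(c("g1", "g2"), c(1000L, 2000L))
  m <- matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- compute_tpm(expr_matrix(m, "raw_counts"), ann)
  # rates 10/1kb and 20/2kb are both 10 -> equal split of the million
  expect_equal(unname(tpm$values[, 1]), c(5e5, 5e5))

  single <- compute_tpm(expr_matrix(matrix(7, 1, 1,
    dimnames = list("g1", "s1")), "raw_counts"),
    gene_annotation("g1", 500L))
  expect_equal(unname(single$values[1, 1]), 1e6)

  sim <- small_sim(seed = 11)
  stpm <- compute_tpm(sim$counts, sim$annotation)
  expect_true(all(abs(colSums(stpm$values) - 1e6) < 1e-6 * 1e6))

  expect_error(compute_tpm(expr_matrix(m, "raw_counts"),
                           gene_annotation("g1", 1000L)), "g2")
  zero <- matrix(c(1, 0), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_error(compute_tpm(expr_matrix(zero, "raw_counts"),
                           gene_annotation("g1", 100L)), "all-zero")
})

test_that("log transform is log2(x + 1)", {
  m <- matrix(c(0, 1, 1e6), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  lg <- log_transform(expr_matrix(m, "tpm"))
  expect_equal(unname(lg$values[, 1]),
               c(0, 1, 19.9315714), tolerance = 1e-7)
  expect_identical(lg$unit, "log2_tpm_plus1")
})

test_that("expression filter keeps genes with mean TPM strictly above threshold", {
  m <- rbind(g_boundary = c(1, 1, 1),
             g_mid      = c(1.5, 1.5, 1.5),
             g_low      = c(0.1, 0.2, 0.1))
  colnames(m) <- paste0("s", 1:3)
  sel <- filter_expressed(expr_matrix(m, "tpm"))
  expect_identical(sel$selected_gene_ids, "g_mid")
  # brute-force oracle on a random matrix
  set.seed(31)
  r <- matrix(rexp(2000, rate = 1), 200, 10,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:10)))
  x <- expr_matrix(r, "tpm")
  expect_identical(filter_expressed(x)$selected_gene_ids,
                   rownames(r)[apply(r, 1, mean) > 1])
})

test_that("top-quartile variance selection takes floor(n/4) by log-scale variance", {
  # the in-print count: 19,261 genes yield exactly 4,815
  expect_equal(floor(19261 / 4), 4815)
  x <- random_logtpm(1000, 8, seed = 41)
  sel <- select_top_quartile_variance(x)
  expect_length(sel$selected_gene_ids, 250)
  # independent sort-based oracle
  v <- apply(x$values, 1, var)
  oracle <- names(sort(v, decreasing = TRUE))[1:250]
  expect_setequal(sel$selected_gene_ids, oracle)
  # row permutation invariance
  perm <- expr_matrix(x$values[sample(nrow(x$values)), ], "log2_tpm_plus1")
  expect_setequal(select_top_quartile_variance(perm)$selected_gene_ids,
                  sel$selected_gene_ids)
  # 4 genes with distinct variances: only the top one survives
  m4 <- rbind(g1 = c(0, 4), g2 = c(0, 3), g3 = c(0, 2), g4 = c(0, 1))
  colnames(m4) <- c("s1", "s2")
  expect_identical(
    select_top_quartile_variance(expr_matrix(m4, "log2_tpm_plus1"))$selected_gene_ids,
    "g1")
  expect_error(select_top_quartile_variance(
    expr_matrix(m4[1:3, ], "log2_tpm_plus1")), "at least 4")
})

test_that("top-expressed selection ranks by within-cell-type mean", {
  m <- rbind(hi = c(5, 5, 1, 1), lo = c(3, 3, 9, 9))
  colnames(m) <- paste0("s", 1:4)
  x <- expr_matrix(m, "log2_tpm_plus1")
  ind <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
                dimnames = list(paste0("s", 1:4), c("ctA", "ctB")))
  tr <- trait_design(ind)
  expect_identical(select_top_expressed(x, tr, "ctA", 1)$selected_gene_ids, "hi")
  expect_identical(select_top_expressed(x, tr, "ctB", 1)$selected_gene_ids, "lo")
  expect_setequal(select_top_expressed(x, tr, "ctA", 2)$selected_gene_ids,
                  c("hi", "lo"))
  expect_error(select_top_expressed(x, tr, "ctC", 1), "ctC")
  # sort oracle on a larger instance
  y <- random_logtpm(500, 4, seed = 17)
  ind2 <- ind
  rownames(ind2) <- colnames(y$values)
  tr2 <- trait_design(ind2)
  sel <- select_top_expressed(y, tr2, "ctA", 100)
  oracle <- names(sort(rowMeans(y$values[, c("s01", "s02")]),
                       decreasing = TRUE))[1:100]
  expect_setequal(sel$selected_gene_ids, oracle)
})

test_that("sample PCA matches an independent eigendecomposition", {
  x <- random_logtpm(50, 10, seed = 23)
  pc <- pca_samples(x)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_equal(sum(pc$variance_explained), 1, tolerance = 1e-8)
  # oracle: eigendecomposition of the sample covariance of centered data
  xs <- t(x$values)
  xc <- scale(xs, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc), symmetric = TRUE)
  k <- ncol(pc$scores)
  for (j in seq_len(min(3, k))) {
    sc <- xc %*% ev$vectors[, j]
    expect_lt(min(max(abs(sc - pc$scores[, j])),
                  max(abs(sc + pc$scores[, j]))), 1e-8)
  }
  # duplicated samples get identical scores
  dup <- x$values[, c(1, 1, 2:10)]
  colnames(dup) <- c("d1", "d2", colnames(x$values)[2:10])
  pcd <- pca_samples(expr_matrix(dup, "log2_tpm_plus1"))
  expect_equal(pcd$scores["d1", ], pcd$scores["d2", ], ignore_attr = TRUE)
  # collinear samples: a single component explains everything
  g <- outer(seq_len(20), c(1, 2, 3))
  dimnames(g) <- list(sprintf("g%02d", 1:20), c("a", "b", "c"))
  pc1 <- pca_samples(expr_matrix(g, "log2_tpm_plus1"))
  expect_equal(pc1$variance_explained[1], 1, tolerance = 1e-10)
})
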
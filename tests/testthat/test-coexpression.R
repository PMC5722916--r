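make_expr <- function(m) {
  dimnames(m) <- list(sprintf("g%02d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  expr_matrix(m, "log2_tpm_plus1")
}

test_that("signed-hybrid adjacency powers positive correlations and zeroes negatives", {
  x <- c(1, 2, 3, 4, 5)
  e <- make_expr(rbind(x, 2 * x + 1, -x + 10))
  a <- signed_hybrid_adjacency(e, 16)
  expect_equal(a["g01", "g02"], 1)           # cor = 1 for any power
  expect_equal(a["g01", "g03"], 0)           # anti-correlated pairs drop out
  expect_equal(diag(a), rep(0, 3), ignore_attr = TRUE)

  set.seed(51)
  y <- make_expr(matrix(rnorm(200), 20, 10))
  r <- cor(t(y$values))
  a2 <- signed_hybrid_adjacency(y, 16)
  i <- which(r > 0 & upper.tri(r))[1]
  expect_equal(a2[i], r[i]^16)               # e.g. 0.9^16 = 0.18530...
  expect_identical(a2, t(a2))
  expect_true(all(a2 >= 0 & a2 <= 1))
  flat <- make_expr(rbind(x, rep(2, 5)))
  expect_error(signed_hybrid_adjacency(flat, 6), "zero-variance")
})

test_that("scale-free fit is 1 on collinear bins and low on binomial degrees", {
  # degrees 1, 2, 3 with multiplicities 36, 9, 4: counts proportional to
  # k^-2, so log p is exactly linear in log k across the three bins
  k <- rep(c(1, 2, 3), c(36, 9, 4))
  n <- length(k)
  a <- matrix(k / (n - 1), n, n)   # row sums are exactly k (only they matter)
  diag(a) <- 0
  # lm warns about the (intended) perfect fit
  f <- suppressWarnings(scale_free_fit(a))
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_lt(f$slope, 0)

  # Erdos-Renyi-like adjacency: concentrated binomial degrees fit poorly
  r2s <- vapply(1:10, function(sd) {
    set.seed(sd)
    n <- 100
    m <- matrix(0, n, n)
    idx <- which(upper.tri(m))
    m[idx[runif(length(idx)) < 0.3]] <- 1
    scale_free_fit(m + t(m))$r2
  }, numeric(1))
  expect_lt(mean(r2s), 0.5)

  expect_error(scale_free_fit(matrix(1, 20, 20) - diag(20)), "equal")
  one_bin <- matrix(0, 20, 20)     # one usable bin: zero-k bin is excluded
  one_bin[1, 2] <- one_bin[2, 1] <- 1e-9
  expect_error(scale_free_fit(one_bin), "bins")
})

test_that("soft-threshold choice honors the target and connectivity monotonicity", {
  sim <- simulate_expression(sim_config(seed = 11))
  lg <- log_transform(compute_tpm(sim$counts, sim$annotation))
  sel <- select_top_quartile_variance(lg, filter_expressed(
    compute_tpm(sim$counts, sim$annotation))$selected_gene_ids)
  ne <- expr_matrix(lg$values[sel$selected_gene_ids, ], "log2_tpm_plus1")
  pick <- pick_soft_threshold(ne)
  row <- pick$fits[pick$fits$power == pick$power, ]
  expect_true(pick$reached_target)
  expect_gte(row$r2, 0.9)
  expect_lt(row$slope, 0)
  # mean connectivity non-increasing in the power
  expect_true(all(diff(pick$fits$mean_k) <= 1e-9))
  # target 0: smallest candidate wins
  expect_equal(pick_soft_threshold(ne, candidate_powers = c(2, 4, 6),
                                   target_r2 = 1e-12)$power, 2)
})

test_that("topological overlap matches hand-computed cases", {
  # complete unit-weight graph on 4 genes: l = 2, k = 3 -> TOM = 1
  a4 <- matrix(1, 4, 4) - diag(4)
  dimnames(a4) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_true(all(abs(topological_overlap(a4) - 1) < 1e-12))
  # two genes connected only to each other: (0+1)/(1+1-1) = 1
  a2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(topological_overlap(a2)["a", "b"], 1)
  # empty adjacency: off-diagonal TOM is 0
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tz <- topological_overlap(z)
  expect_true(all(tz[upper.tri(tz)] == 0))
  expect_equal(diag(tz), rep(1, 3), ignore_attr = TRUE)
  # symmetry and range on a random instance
  set.seed(5)
  x <- make_expr(matrix(rnorm(300), 30, 10))
  tom <- topological_overlap(signed_hybrid_adjacency(x, 6))
  expect_identical(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1))
})

test_that("gene clustering reproduces a naive average-linkage oracle", {
  set.seed(61)
  x <- make_expr(matrix(rnorm(80), 8, 10))
  tom <- topological_overlap(signed_hybrid_adjacency(x, 2))
  tree <- cluster_genes(tom)
  coph <- as.matrix(cophenetic(tree))
  d <- 1 - tom
  diag(d) <- 0
  oracle <- oracle_avg_linkage_cophenetic(d)
  expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
               tolerance = 1e-12)
  # exact duplicate genes are the most similar pair and merge first
  dupx <- make_expr(rbind(x$values[1, ], x$values[1, ], x$values[2:4, ]))
  tomd <- topological_overlap(signed_hybrid_adjacency(dupx, 2))
  treed <- cluster_genes(tomd)
  expect_equal(min(treed$height), treed$height[1])
  expect_setequal(treed$merge[1, ], c(-1, -2))
})

test_that("tree cut recovers planted blocks and handles degenerate input", {
  # two blocks of 40 genes with high within-block TOM
  set.seed(71)
  act <- matrix(rnorm(2 * 20), 2, 20)
  m <- rbind(
    act[rep(1, 40), ] * 0.95 + matrix(rnorm(40 * 20, sd = 0.3), 40, 20),
    act[rep(2, 40), ] * 0.95 + matrix(rnorm(40 * 20, sd = 0.3), 40, 20))
  x <- make_expr(m)
  tom <- topological_overlap(signed_hybrid_adjacency(x, 6))
  labels <- cut_tree(cluster_genes(tom), min_module_size = 30)
  expect_equal(max(labels), 2)
  expect_equal(sum(labels == 0), 0)
  truth <- rep(1:2, each = 40)
  expect_equal(mclust::adjustedRandIndex(truth, labels), 1)
  # min size above n: everything unassigned
  expect_true(all(cut_tree(cluster_genes(tom), min_module_size = 100) == 0))
  # pure noise: at most one module
  noise_mods <- vapply(1:10, function(sd) {
    set.seed(sd)
    nx <- make_expr(matrix(rnorm(50 * 20), 50, 20))
    nt <- topological_overlap(signed_hybrid_adjacency(nx, 6))
    max(cut_tree(cluster_genes(nt), min_module_size = 30))
  }, numeric(1))
  expect_true(all(noise_mods <= 1))
})

test_that("module eigengene is the leading PC, correctly oriented", {
  profile <- c(1, 5, 2, 8, 3, 9)
  x <- make_expr(rbind(profile, profile * 2 + 3, profile * 0.5 - 1))
  eg <- module_eigengene(x, gene_ids(x))
  expect_equal(abs(cor(eg, profile)), 1, tolerance = 1e-12)
  expect_gt(cor(eg, profile), 0)              # oriented with the mean profile
  expect_equal(sum(eg^2), 1)                  # unit norm
  # single-gene module: that gene standardized and normalized
  eg1 <- module_eigengene(x, "g01")
  z <- scale(profile)[, 1]
  expect_equal(unname(eg1), z / sqrt(sum(z^2)), tolerance = 1e-12)
  # planted module: eigengene tracks the true latent activity
  sim <- simulate_expression(sim_config(seed = 13))
  lg <- log_transform(compute_tpm(sim$counts, sim$annotation))
  mem <- names(sim$truth$module_labels)[sim$truth$module_labels == 1]
  ege <- module_eigengene(lg, mem)
  expect_gte(abs(cor(ege, sim$truth$activity["M1", ])), 0.9)
  # explained variance of the eigengene direction >= mean-profile direction
  xs <- t(scale(t(lg$values[mem, ])))
  vf <- function(v) sum((xs %*% v / sqrt(sum(v^2)))^2)
  mp <- colMeans(xs)
  expect_gte(vf(ege) + 1e-9, vf(mp))
})

test_that("module merging fuses shared-activity modules and terminates", {
  sim <- simulate_expression(sim_config(seed = 19))
  lg <- log_transform(compute_tpm(sim$counts, sim$annotation))
  labels <- sim$truth$module_labels
  # split planted module 1 into two halves: same latent activity
  mem <- names(labels)[labels == 1]
  fake <- setNames(integer(length(labels)), names(labels))
  fake[mem[1:25]] <- 1
  fake[mem[26:50]] <- 2
  merged <- merge_modules(lg, fake)
  expect_equal(max(merged), 1)
  expect_setequal(names(merged)[merged == 1], mem)
  # independent activities stay apart
  two <- setNames(integer(length(labels)), names(labels))
  two[labels == 1] <- 1
  two[labels == 2] <- 2
  kept <- merge_modules(lg, two)
  expect_equal(max(kept), 2)
  # single module unchanged
  one <- setNames(integer(length(labels)), names(labels))
  one[labels == 1] <- 1
  expect_equal(max(merge_modules(lg, one)), 1)
})

test_that("K_ME membership is the gene-eigengene correlation with overlap allowed", {
  sim <- simulate_expression(sim_config(seed = 13))
  lat <- expr_matrix(sim$truth$latent, "log2_tpm_plus1")
  labels <- sim$truth$module_labels
  mem <- names(labels)[labels == 1]
  eg <- rbind(M1 = module_eigengene(lat, mem))
  colnames(eg) <- colnames(lat$values)
  kme <- module_membership(lat, eg)
  expect_true(all(kme >= -1 & kme <= 1))
  # members built with mean loading 0.9 average K_ME ~ 0.9
  expect_lt(abs(mean(kme[mem, "M1"]) - 0.9), 0.05)
  # independent noise genes essentially never reach the 0.75 bar (n = 26)
  bg <- names(labels)[labels == 0]
  expect_lt(mean(abs(kme[bg, "M1"]) > 0.75), 0.01)
  sets <- assign_by_kme(kme, 0.75)
  expect_true(all(sets$M1 %in% rownames(kme)[kme[, "M1"] > 0.75]))
  # single-gene module: K_ME of that gene is exactly 1
  eg1 <- rbind(M1 = module_eigengene(lat, mem[1]))
  colnames(eg1) <- colnames(lat$values)
  expect_equal(module_membership(lat, eg1)[mem[1], "M1"], 1, tolerance = 1e-12)
})

test_that("module-trait correlation uses the Student-t reference", {
  ind <- matrix(0, 26, 2, dimnames = list(sprintf("s%02d", 1:26), c("A", "B")))
  ind[1:13, "A"] <- 1
  ind[14:26, "B"] <- 1
  tr <- trait_design(ind)
  # eigengene equal to the (centered) indicator: r = 1, p ~ 0
  eg <- rbind(M1 = as.numeric(scale(ind[, "A"])))
  colnames(eg) <- rownames(ind)
  mt <- module_trait_correlation(eg, tr)
  expect_equal(mt$r["M1", "A"], 1, tolerance = 1e-12)
  expect_lt(mt$p["M1", "A"], 1e-12)
  # an eigengene constructed to have exactly r = 0.5 with n = 26:
  # t = 0.5 sqrt(24)/sqrt(0.75) = 2.8284, two-sided p = 0.00929
  set.seed(3)
  zi <- as.numeric(scale(ind[, "A"]))
  resid <- rnorm(26)
  resid <- resid - zi * sum(resid * zi) / sum(zi^2)
  y <- 0.5 * zi / sd(zi) + sqrt(0.75) * resid / sd(resid)
  eg2 <- rbind(M1 = y)
  colnames(eg2) <- rownames(ind)
  mt2 <- module_trait_correlation(eg2, tr)
  expect_equal(mt2$r["M1", "A"], 0.5, tolerance = 1e-10)
  expect_equal(mt2$p["M1", "A"], 0.0092937, tolerance = 1e-4)
  # r = 0 gives p = 1
  orth <- rbind(M1 = resid / sqrt(sum(resid^2)))
  colnames(orth) <- rownames(ind)
  mt0 <- module_trait_correlation(orth, tr)
  expect_equal(unname(mt0$p["M1", "A"]), 1, tolerance = 1e-10)
})
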
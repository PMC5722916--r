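test_that("hypergeometric upper tail matches exact enumeration", {
  expect_equal(hypergeom_upper_tail(10, 5, 5, 0), 1)
  # all 5 draws successes: 1 / C(10,5) = 1/252
  expect_equal(hypergeom_upper_tail(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  # log-space summation oracle, including the protein-atlas population
  # (19,628 genes, 354 placenta-specific)
  set.seed(91)
  for (i in 1:200) {
    N <- sample(20:5000, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    p <- hypergeom_upper_tail(N, K, n, k)
    expect_equal(p, oracle_hyper_upper(N, K, n, k), tolerance = 1e-10)
  }
  for (k in c(0, 5, 18, 40, 90)) {
    expect_equal(hypergeom_upper_tail(19628, 354, 1000, k),
                 oracle_hyper_upper(19628, 354, 1000, k), tolerance = 1e-10)
  }
  # non-increasing in k
  ps <- vapply(0:50, function(k) hypergeom_upper_tail(19628, 354, 1000, k),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_upper_tail(10, 11, 5, 2), "inconsistent")
  expect_error(hypergeom_upper_tail(10, 5, 5, 6), "inconsistent")
})

test_that("tissue-specificity scan ranks the truly enriched tissue first", {
  sim <- small_sim(seed = 17)
  universe <- gene_ids(sim$counts)
  placenta <- sim$truth$tissue_sets[["CT1"]]
  res <- tissue_specificity_scan(placenta, sim$annotation, universe)
  expect_equal(res$set_name[1], "CT1")
  expect_equal(res$k[res$set_name == "CT1"], length(placenta))
  # disjoint query: every p is 1
  others <- setdiff(universe, unlist(sim$truth$tissue_sets))[1:50]
  res0 <- tissue_specificity_scan(others, sim$annotation, universe)
  expect_true(all(res0$p_value == 1))
  expect_error(tissue_specificity_scan("gX", sim$annotation, universe),
               "outside")
})

test_that("up-regulation filter applies inclusive fold-change and FDR bounds", {
  de <- de_table(paste0("g", 1:6),
                 log2_fold_change = c(1.0, 3, 1.5, -1.5, -0.5, 0.5),
                 p_value = rep(0.001, 6),
                 p_adjusted = c(0.01, 0.02, 0.001, 0.001, 0.001, 0.5))
  up <- upregulated_sets(de)
  expect_setequal(up$up_in_a, c("g1", "g3"))  # boundary |FC|=2, padj=0.01 in
  expect_setequal(up$up_in_b, "g4")           # g2 fails padj, g5 fails FC
  expect_length(intersect(up$up_in_a, up$up_in_b), 0)
})

test_that("randomization test matches exhaustive enumeration and is reproducible", {
  universe <- paste0("u", 1:6)
  target <- paste0("u", 1:3)
  module <- c("u1", "u4")          # overlap 1
  # exact null over all C(6,2)=15 modules: P(overlap > 1) = 3/15
  res <- randomization_module_test(module, target, universe,
                                   n_random = 20000, seed = 7)
  expect_equal(res$observed, 1)
  expect_lt(abs(res$p_value - 0.2), 3 * sqrt(0.2 * 0.8 / 20000))
  # bitwise reproducibility
  res2 <- randomization_module_test(module, target, universe,
                                    n_random = 20000, seed = 7)
  expect_identical(res$p_value, res2$p_value)
  # maximal observed overlap: no null draw can exceed it
  res3 <- randomization_module_test(c("u1", "u2", "u3"), target, universe,
                                    n_random = 2000, seed = 1)
  expect_equal(res3$p_value, 0)
  expect_match(capture.output(print(res3)), "< 0.0005", all = FALSE)
  # >= convention is available and never smaller
  res4 <- randomization_module_test(module, target, universe,
                                    n_random = 5000, seed = 2,
                                    convention = "geq")
  res5 <- randomization_module_test(module, target, universe,
                                    n_random = 5000, seed = 2)
  expect_gte(res4$p_value, res5$p_value)
  expect_error(randomization_module_test(paste0("u", 1:7), target, universe,
                                         seed = 1), "universe|contained")
})

test_that("Benjamini-Hochberg adjustment is step-up with monotone enforcement", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gene-set enrichment applies the FDR / fold / minimum-gene filter", {
  universe <- sprintf("g%04d", 1:2000)
  withr::with_seed(23, {
    query <- sample(universe, 100)
    planted <- c(sample(query, 60), sample(setdiff(universe, query), 40))
    sets <- c(list(planted = planted),
              lapply(1:10, function(i) sample(universe, 100)))
    names(sets) <- c("planted", paste0("rnd", 1:10))
  })
  gsc <- gene_set_collection(sets, universe)
  res <- gene_set_enrichment(query, gsc)
  expect_equal(res$set_name[1], "planted")
  expect_true(res$passes_filter[res$set_name == "planted"])
  # small-overlap sets cannot pass no matter how small the p-value
  tiny <- gene_set_collection(list(s = universe[1:4]), universe)
  r2 <- gene_set_enrichment(universe[1:4], tiny)
  expect_equal(r2$k, 4)
  expect_false(r2$passes_filter)
  # a query equal to one set, disjoint from the rest, tops the ranking
  disj <- gene_set_collection(list(a = universe[1:30], b = universe[31:60]),
                              universe)
  r3 <- gene_set_enrichment(universe[1:30], disj)
  expect_equal(r3$set_name[1], "a")
  expect_equal(r3$k[1], r3$n[1])
})

test_that("a planted enriched term is the lone filter-passer across seeds", {
  hits <- vapply(1:20, function(sd) {
    universe <- sprintf("g%04d", 1:2000)
    withr::with_seed(sd, {
      query <- sample(universe, 100)
      planted <- c(sample(query, 60), sample(setdiff(universe, query), 40))
      sets <- c(list(planted = planted),
                lapply(1:30, function(i) sample(universe, 100)))
      names(sets) <- c("planted", paste0("rnd", 1:30))
    })
    res <- gene_set_enrichment(query, gene_set_collection(sets, universe))
    passers <- res$set_name[res$passes_filter]
    identical(passers, "planted")
  }, logical(1))
  expect_gte(sum(hits), 18)
})
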
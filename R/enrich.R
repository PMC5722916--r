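#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of observing at
#' least `k` successes when drawing `n` genes without replacement from a
#' population of `N` genes of which `K` are successes. Computed via the
#' log-space distribution function, so extreme tails (e.g. the protein-atlas
#' population of 19,628 genes with 354 placenta-specific ones) are exact to
#' machine precision.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param k Observed successes.
#' @param log_p Return the natural log of the tail probability instead;
#'   useful when the tail is too extreme for a double (below ~1e-308).
#' @return The upper-tail probability in \[0, 1\] (or its log).
#' @examples
#' hypergeom_upper_tail(10, 5, 5, 5)   # 1 / choose(10, 5)
#' @export
hypergeom_upper_tail <- function(N, K, n, k, log_p = FALSE) {
  for (v in list(N, K, n, k)) assert_scalar_num(v, "count")
  if (any(c(N, K, n, k) != round(c(N, K, n, k))) ||
      K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n))
    abort("inconsistent hypergeometric counts (need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n))")
  if (k == 0) return(if (log_p) 0 else 1)
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  if (log_p) lp else exp(lp)
}

#' Tissue-specificity enrichment scan
#'
#' For every tissue named in the annotation, tests whether the query genes
#' are enriched for genes specific to that tissue (any of the tissue
#' enriched / group enriched / tissue enhanced categories), using the
#' hypergeometric upper tail over the supplied universe.
#'
#' @param top_genes Character vector of query genes (e.g. the 1,000 most
#'   highly expressed genes of a cell type); must be contained in `universe`.
#' @param annotation A [gene_annotation()] covering the universe.
#' @param universe Character vector of gene ids defining the population. By
#'   default this should be the annotated genes present in the expression
#'   data; pass the full database gene list for a database-wide population.
#' @return A data.frame sorted by p-value with columns `set_name`, `N`, `K`,
#'   `n`, `k`, `p_value`, `fold_enrichment`.
#' @export
tissue_specificity_scan <- function(top_genes, annotation, universe) {
  if (!length(universe)) abort("empty universe")
  if (any(!top_genes %in% universe))
    abort("query genes outside the universe")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  tissues <- sort(unique(unlist(ann$specific_tissues)))
  N <- length(universe)
  n <- length(unique(top_genes))
  rows <- lapply(tissues, function(tis) {
    in_tis <- vapply(ann$specific_tissues, function(v) tis %in% v, logical(1))
    tset <- ann$gene_id[in_tis]
    K <- length(tset)
    k <- length(intersect(top_genes, tset))
    data.frame(set_name = tis, N = N, K = K, n = n, k = k,
               p_value = hypergeom_upper_tail(N, K, n, k),
               fold_enrichment = if (K > 0) (k / n) / (K / N) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a DE table into up-regulated gene sets
#'
#' A gene is called up-regulated when its absolute fold-change is at least
#' `fc_threshold` and its adjusted p-value at most `padj_threshold`
#' (boundaries inclusive). Genes with positive log2 fold-change are up in
#' condition A, negative in condition B; the two sets are always disjoint.
#'
#' @param de A [de_table()].
#' @param fc_threshold Minimum absolute (linear) fold-change (default 2).
#' @param padj_threshold Maximum adjusted p (default 0.01).
#' @return A list with character vectors `up_in_a` and `up_in_b`.
#' @export
upregulated_sets <- function(de, fc_threshold = 2, padj_threshold = 0.01) {
  lfc_min <- log2(fc_threshold)
  sig <- !is.na(de$p_adjusted) & de$p_adjusted <= padj_threshold
  list(up_in_a = de$gene_id[sig & de$log2_fold_change >= lfc_min],
       up_in_b = de$gene_id[sig & de$log2_fold_change <= -lfc_min])
}

#' Size-matched randomization test for module/gene-set overlap
#'
#' Draws `n_random` gene sets of the module's size uniformly (without
#' replacement within each draw) from the universe, counts each draw's
#' overlap with `target_set`, and reports
#' `p = #(null overlap > observed) / n_random` — the strictly-greater
#' convention, which is conservative near p = 0; a reported 0 means
#' p < 1/n_random. Set `convention = "geq"` for the >= variant.
#'
#' @param module_genes Character vector (the observed module).
#' @param target_set Character vector (e.g. genes up-regulated in a
#'   condition).
#' @param universe Character vector containing both.
#' @param n_random Number of random modules (default 10000).
#' @param seed Mandatory integer seed; results are bit-reproducible.
#' @param convention `"greater"` (default, as defined above) or `"geq"`.
#' @return A list of class `randomization_result`: `observed`, `p_value`,
#'   `n_random`, `null_summary`, `seed`, `convention`.
#' @export
randomization_module_test <- function(module_genes, target_set, universe,
                                      n_random = 10000, seed,
                                      convention = c("greater", "geq")) {
  convention <- match.arg(convention)
  if (missing(seed)) abort("'seed' is mandatory")
  module_genes <- unique(module_genes)
  if (length(module_genes) > length(universe))
    abort("module larger than the universe")
  if (any(!module_genes %in% universe) || any(!target_set %in% universe))
    abort("module and target set must be contained in the universe")
  m <- length(module_genes)
  N <- length(universe)
  in_target <- universe %in% target_set
  observed <- length(intersect(module_genes, target_set))
  null <- withr::with_seed(as.integer(seed),
    vapply(seq_len(n_random),
           function(i) sum(in_target[sample.int(N, m)]), integer(1)))
  hits <- if (convention == "greater") sum(null > observed)
          else sum(null >= observed)
  structure(list(observed = observed,
                 p_value = hits / n_random,
                 n_random = n_random,
                 null_summary = c(mean = mean(null), sd = stats::sd(null),
                                  max = as.numeric(max(null))),
                 seed = as.integer(seed),
                 convention = convention),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  p_show <- if (x$p_value == 0) sprintf("< %g", 1 / x$n_random)
            else format(x$p_value)
  cat(sprintf("randomization test: observed overlap %d, p %s (%d draws)\n",
              x$observed, p_show, x$n_random))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving and elementwise no smaller than the input.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric gene-set enrichment with significance filters
#'
#' Per-set hypergeometric upper-tail test of the query against each set in
#' the collection, over the collection's universe, with BH-FDR across sets.
#' A set passes the filter when FDR <= `fdr_max`, fold enrichment
#' `(k/n)/(K/N)` >= `fold_min`, and at least `min_genes` query genes hit it.
#'
#' @param query_genes Character vector, contained in the collection's
#'   universe.
#' @param collection A [gene_set_collection()].
#' @param min_genes Minimum query genes in a set for it to pass (default 5).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param fold_min Fold-enrichment cutoff (default 1.5).
#' @return A data.frame sorted by p-value: `set_name`, `N`, `K`, `n`, `k`,
#'   `p_value`, `fold_enrichment`, `fdr`, `passes_filter`.
#' @export
gene_set_enrichment <- function(query_genes, collection, min_genes = 5,
                                fdr_max = 0.05, fold_min = 1.5) {
  if (!inherits(collection, "gene_set_collection"))
    abort("'collection' must be a gene_set_collection")
  if (!length(collection$sets)) abort("empty gene-set collection")
  query <- unique(query_genes)
  if (any(!query %in% collection$universe))
    abort("query genes outside the collection universe")
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(query, set))
    data.frame(set_name = nm, N = N, K = K, n = n, k = k,
               p_value = hypergeom_upper_tail(N, K, n, k),
               fold_enrichment = if (K > 0 && n > 0) (k / n) / (K / N) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$passes_filter <- out$fdr <= fdr_max &
    out$fold_enrichment >= fold_min & out$k >= min_genes
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
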
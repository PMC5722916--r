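#' TPM normalization of a count matrix
#'
#' Transcripts per million: each count is first normalized by gene length
#' (per kilobase) and then by the per-sample sum of those length-normalized
#' rates, scaled to 1e6 — so every sample column sums to exactly one million
#' and values are comparable across genes and libraries.
#'
#' @param counts An `expr_matrix` with unit `"raw_counts"`.
#' @param annotation A [gene_annotation()] covering every gene in `counts`.
#' @return An `expr_matrix` with unit `"tpm"`.
#' @examples
#' m <- matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' ann <- gene_annotation(c("g1", "g2"), c(1000, 2000))
#' compute_tpm(expr_matrix(m, "raw_counts"), ann)$values
#' @export
compute_tpm <- function(counts, annotation) {
  if (!inherits(counts, "expr_matrix") || counts$unit != "raw_counts")
    abort("'counts' must be an expr_matrix of raw counts")
  gid <- gene_ids(counts)
  miss <- setdiff(gid, annotation$gene_id)
  if (length(miss))
    abort("genes missing a length in the annotation: %s%s",
          paste(utils::head(miss, 5), collapse = ", "),
          if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5) else "")
  len_kb <- annotation$length_bp[match(gid, annotation$gene_id)] / 1000
  rate <- counts$values / len_kb
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero))
    abort("sample(s) with all-zero counts: %s",
          paste(colnames(counts$values)[zero], collapse = ", "))
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  expr_matrix(tpm, "tpm")
}

#' Log-transform TPM values
#'
#' Applies `log2(x + 1)` elementwise: monotone and zero-preserving.
#'
#' @param tpm An `expr_matrix` with unit `"tpm"`.
#' @return An `expr_matrix` with unit `"log2_tpm_plus1"`.
#' @export
log_transform <- function(tpm) {
  if (!inherits(tpm, "expr_matrix") || tpm$unit != "tpm")
    abort("'tpm' must be an expr_matrix of TPM values")
  if (any(tpm$values < 0)) abort("negative values cannot be log-transformed")
  expr_matrix(log2(tpm$values + 1), "log2_tpm_plus1")
}

new_selection <- function(ids, criterion, parameters) {
  structure(list(selected_gene_ids = ids, criterion = criterion,
                 parameters = parameters), class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("gene_selection: %d genes by '%s'\n",
              length(x$selected_gene_ids), x$criterion))
  invisible(x)
}

#' Keep genes expressed above a TPM threshold
#'
#' A gene is retained when its mean TPM across all samples is strictly
#' greater than `threshold`. The mean-across-samples rule gives a single
#' number per gene; set `rule` to `"any_sample"` or `"all_samples"` for the
#' per-sample variants.
#'
#' @param tpm An `expr_matrix` with unit `"tpm"`.
#' @param threshold TPM cutoff (default 1), strict inequality.
#' @param rule How per-sample values are combined before thresholding.
#' @return A `gene_selection` (criterion `"tpm_gt1"`), genes in input order.
#' @export
filter_expressed <- function(tpm, threshold = 1,
                             rule = c("mean", "any_sample", "all_samples")) {
  rule <- match.arg(rule)
  if (!inherits(tpm, "expr_matrix") || tpm$unit != "tpm")
    abort("'tpm' must be an expr_matrix of TPM values")
  keep <- switch(rule,
    mean        = rowMeans(tpm$values) > threshold,
    any_sample  = apply(tpm$values > threshold, 1, any),
    all_samples = apply(tpm$values > threshold, 1, all))
  new_selection(gene_ids(tpm)[keep], "tpm_gt1",
                list(threshold = threshold, rule = rule))
}

#' Select the top quartile of genes by expression variance
#'
#' Computes the unbiased (n-1 denominator) sample variance of each gene's
#' log2(TPM+1) profile across all samples and returns the `floor(n/4)` genes
#' of highest variance — e.g. 19,261 input genes yield exactly 4,815. Ties at
#' the cut are broken lexicographically by gene id, so the selection is
#' deterministic and invariant to row order.
#'
#' @param logtpm An `expr_matrix` with unit `"log2_tpm_plus1"`.
#' @param genes Optional subset of gene ids to rank (default: all).
#' @return A `gene_selection` (criterion `"top_quartile_variance"`), selected
#'   genes ordered by decreasing variance.
#' @export
select_top_quartile_variance <- function(logtpm, genes = NULL) {
  if (!inherits(logtpm, "expr_matrix") || logtpm$unit != "log2_tpm_plus1")
    abort("'logtpm' must be an expr_matrix of log2(TPM+1) values")
  if (is.null(genes)) genes <- gene_ids(logtpm)
  miss <- setdiff(genes, gene_ids(logtpm))
  if (length(miss)) abort("unknown genes: %s", paste(utils::head(miss, 5), collapse = ", "))
  if (length(genes) < 4) abort("need at least 4 genes to take a quartile")
  v <- apply(logtpm$values[genes, , drop = FALSE], 1, stats::var)
  ord <- order(-v, names(v))          # variance desc, gene id asc on ties
  n_keep <- floor(length(genes) / 4)
  new_selection(names(v)[ord][seq_len(n_keep)], "top_quartile_variance",
                list(n_input = length(genes), n_selected = n_keep))
}

#' Select the most highly expressed genes in one cell type
#'
#' Ranks genes by mean log2(TPM+1) over the replicates of `cell_type` and
#' returns the top `n`; ties broken lexicographically by gene id.
#'
#' @param logtpm An `expr_matrix` with unit `"log2_tpm_plus1"`.
#' @param traits A [trait_design()] aligned with `logtpm`'s samples.
#' @param cell_type Cell-type name (a column of the traits design).
#' @param n Number of genes to return (default 1000).
#' @return A `gene_selection` (criterion `"top_n_expressed"`), genes ordered
#'   by decreasing mean expression.
#' @export
select_top_expressed <- function(logtpm, traits, cell_type, n = 1000) {
  if (!inherits(logtpm, "expr_matrix") || logtpm$unit != "log2_tpm_plus1")
    abort("'logtpm' must be an expr_matrix of log2(TPM+1) values")
  if (!cell_type %in% colnames(traits$indicator))
    abort("unknown cell type '%s'", cell_type)
  if (n > nrow(logtpm$values)) abort("n exceeds the number of genes")
  samp <- rownames(traits$indicator)[traits$indicator[, cell_type] == 1]
  samp <- intersect(sample_ids(logtpm), samp)
  if (!length(samp)) abort("no samples of cell type '%s' in the matrix", cell_type)
  m <- rowMeans(logtpm$values[, samp, drop = FALSE])
  ord <- order(-m, names(m))
  new_selection(names(m)[ord][seq_len(n)], "top_n_expressed",
                list(cell_type = cell_type, n = n))
}

#' Principal components of samples over a gene selection
#'
#' Centers each gene across samples and decomposes the samples x genes
#' matrix. Component signs are fixed by making the largest-magnitude gene
#' loading of each component positive, so results are reproducible.
#'
#' @param logtpm An `expr_matrix` with unit `"log2_tpm_plus1"`.
#' @param selection Optional `gene_selection` (or character vector of gene
#'   ids) restricting the genes used.
#' @return A list with `scores` (samples x components), `variance_explained`
#'   (fractions, non-increasing, summing to 1) and `loadings` (genes x
#'   components).
#' @export
pca_samples <- function(logtpm, selection = NULL) {
  if (!inherits(logtpm, "expr_matrix"))
    abort("'logtpm' must be an expr_matrix")
  genes <- if (is.null(selection)) gene_ids(logtpm)
           else if (inherits(selection, "gene_selection")) selection$selected_gene_ids
           else selection
  x <- t(logtpm$values[genes, , drop = FALSE])    # samples x genes
  if (nrow(x) < 2) abort("PCA needs at least 2 samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # orient: largest-|loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, variance_explained = ve, loadings = pc$rotation)
}
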
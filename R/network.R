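#' Configuration for weighted co-expression network construction
#'
#' @param power Soft-threshold exponent beta; if `NULL` it is chosen by
#'   [pick_soft_threshold()].
#' @param candidate_powers Ascending candidate betas scanned for scale-free
#'   fit (default `c(1:10, 12, 14, 16, 18, 20)`).
#' @param target_scale_free_r2 Scale-free model fit (R^2) a power must reach
#'   to be selected (default 0.9).
#' @param min_module_size Clusters smaller than this are left unassigned
#'   (default 30).
#' @param merge_cor_threshold Modules whose eigengenes correlate above this
#'   are merged (default 0.75).
#' @param kme_threshold Module-membership correlation granting (possibly
#'   multiple) membership (default 0.75).
#' @param n_degree_bins Equal-width connectivity bins used by the scale-free
#'   fit (default 10).
#' @return A list of class `network_config`.
#' @export
network_config <- function(power = NULL,
                           candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                           target_scale_free_r2 = 0.9,
                           min_module_size = 30,
                           merge_cor_threshold = 0.75,
                           kme_threshold = 0.75,
                           n_degree_bins = 10) {
  if (!is.null(power) && (power < 1)) abort("'power' must be >= 1")
  if (is.unsorted(candidate_powers, strictly = TRUE))
    abort("'candidate_powers' must be ascending")
  for (th in c(target_scale_free_r2, merge_cor_threshold, kme_threshold))
    if (!(th > 0 && th < 1)) abort("thresholds must lie in (0, 1)")
  structure(list(power = power, candidate_powers = candidate_powers,
                 target_scale_free_r2 = target_scale_free_r2,
                 min_module_size = min_module_size,
                 merge_cor_threshold = merge_cor_threshold,
                 kme_threshold = kme_threshold,
                 n_degree_bins = n_degree_bins),
            class = "network_config")
}

gene_cor <- function(expr) {
  x <- expr$values
  v <- apply(x, 1, stats::var)
  flat <- v == 0 | is.na(v)
  if (any(flat))
    abort("zero-variance gene(s): %s",
          paste(utils::head(rownames(x)[flat], 5), collapse = ", "))
  stats::cor(t(x))
}

#' Signed-hybrid soft-thresholded adjacency
#'
#' The co-expression edge weight between genes i and j is `cor(i, j)^beta`
#' when the Pearson correlation is positive and 0 otherwise (the
#' "signed hybrid" convention: anti-correlated genes are unconnected rather
#' than connected). The diagonal is 0.
#'
#' @param expr An `expr_matrix` of log2(TPM+1) values (genes x samples,
#'   >= 3 samples, no zero-variance gene).
#' @param power Soft-threshold exponent beta (>= 1).
#' @return Symmetric genes x genes matrix in \[0, 1\] with zero diagonal.
#' @export
signed_hybrid_adjacency <- function(expr, power) {
  if (!inherits(expr, "expr_matrix")) abort("'expr' must be an expr_matrix")
  if (ncol(expr$values) < 3) abort("need at least 3 samples")
  assert_scalar_num(power, "power")
  if (power < 1) abort("'power' must be >= 1")
  r <- gene_cor(expr)
  a <- ifelse(r > 0, r, 0)^power
  diag(a) <- 0
  a
}

#' Scale-free topology fit of an adjacency matrix
#'
#' Node connectivity `k_i = sum_j a_ij` is binned into `n_bins` equal-width
#' bins; within each non-empty bin the mean connectivity and the frequency
#' `p(k)` are computed, and `log10 p(k)` is regressed on `log10 mean-k`. A
#' scale-free (power-law) degree distribution makes this relationship linear
#' with negative slope; the returned `r2` is the coefficient of
#' determination of that regression.
#'
#' @param adjacency Symmetric adjacency matrix (e.g. from
#'   [signed_hybrid_adjacency()]).
#' @param n_bins Number of connectivity bins (default 10).
#' @return A list with `r2`, `slope`, `mean_k` and the per-bin `table`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- rowSums(adjacency)
  if (length(k) < n_bins) abort("need at least n_bins genes")
  if (diff(range(k)) == 0)
    abort("all connectivities equal; scale-free fit undefined")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  cnt <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  keep <- !is.na(cnt) & !is.na(mean_k) & mean_k > 0
  if (sum(keep) < 2)
    abort("fewer than 2 usable connectivity bins; cannot fit")
  df <- data.frame(log_k = log10(mean_k[keep]),
                   log_p = log10(cnt[keep] / length(k)))
  fit <- stats::lm(log_p ~ log_k, data = df)
  list(r2 = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       mean_k = mean(k),
       table = df)
}

#' Choose the soft-threshold power by scale-free fit
#'
#' Scans the candidate powers in ascending order and returns the smallest
#' whose scale-free fit reaches `target_r2`; if none does, the power with the
#' best fit is returned with `reached_target = FALSE` and a warning. The full
#' per-power table (power, r2, slope, mean connectivity) is returned for
#' reporting.
#'
#' @param expr An `expr_matrix` of log2(TPM+1) values.
#' @param candidate_powers Ascending candidate betas.
#' @param target_r2 Required scale-free fit (default 0.9).
#' @param n_bins Connectivity bins for [scale_free_fit()].
#' @return A list with `power`, `reached_target`, and `fits` (data.frame).
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                                target_r2 = 0.9, n_bins = 10) {
  if (!length(candidate_powers)) abort("no candidate powers supplied")
  if (is.unsorted(candidate_powers, strictly = TRUE))
    abort("'candidate_powers' must be ascending")
  r <- gene_cor(expr)
  rpos <- ifelse(r > 0, r, 0)
  diag(rpos) <- 0
  fits <- data.frame(power = candidate_powers, r2 = NA_real_,
                     slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidate_powers)) {
    a <- rpos^candidate_powers[i]
    f <- tryCatch(scale_free_fit(a, n_bins), error = function(e) NULL)
    if (!is.null(f)) {
      fits$r2[i] <- f$r2; fits$slope[i] <- f$slope; fits$mean_k[i] <- f$mean_k
    }
  }
  ok <- which(!is.na(fits$r2) & fits$r2 >= target_r2)
  if (length(ok)) {
    list(power = candidate_powers[ok[1]], reached_target = TRUE, fits = fits)
  } else {
    if (all(is.na(fits$r2))) abort("scale-free fit failed for every power")
    best <- which.max(fits$r2)
    warn("no candidate power reached scale-free R^2 >= %g; using power %g (R^2 = %.3f)",
         target_r2, candidate_powers[best], fits$r2[best])
    list(power = candidate_powers[best], reached_target = FALSE, fits = fits)
  }
}

#' Topological overlap matrix
#'
#' The topological overlap of genes i and j combines their direct adjacency
#' with the strength of their shared neighborhood:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`. `TOM_ii = 1`, and
#' `1 - TOM` is the clustering dissimilarity.
#'
#' @param adjacency Symmetric adjacency with zero diagonal, entries in
#'   \[0, 1\].
#' @return Symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  if (!isTRUE(all.equal(a, t(a)))) abort("adjacency must be symmetric")
  l <- a %*% a                       # zero diagonal makes u != i,j automatic
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  tom
}

#' Cluster genes by average-linkage hierarchy on 1 - TOM
#'
#' @param tom Topological overlap matrix.
#' @return An [stats::hclust] dendrogram.
#' @export
cluster_genes <- function(tom) {
  stats::hclust(stats::as.dist(1 - tom), method = "average")
}

#' Cut a gene dendrogram into modules
#'
#' Adaptive-height cut: every gap between consecutive merge heights is a
#' candidate cut level, and the tree is cut at the level where the number of
#' clusters of at least `min_module_size` genes is maximal — the height at
#' which the most coherent groups coexist before top-level joins between
#' unrelated groups fuse them. Among ties the largest height wins, so each
#' group is taken at its fullest extent; genes that only attach loosely are
#' intended to be filtered afterwards by the K_ME membership rule (as
#' [detect_modules()] does). Clusters smaller than `min_module_size` are
#' unassigned (label 0). Modules are renumbered 1..M by decreasing size,
#' ties broken by the lexicographically smallest member gene. The procedure
#' is fully deterministic.
#'
#' @param dendrogram An [stats::hclust] tree from [cluster_genes()].
#' @param min_module_size Minimum genes per module (default 30).
#' @return Named integer vector: gene -> module id (0 = unassigned).
#' @export
cut_tree <- function(dendrogram, min_module_size = 30) {
  hs <- sort(unique(dendrogram$height))
  # cut levels between consecutive merges (plus one above the top merge)
  cand <- c((hs[-length(hs)] + hs[-1]) / 2, hs[length(hs)] + 1)
  cuts <- stats::cutree(dendrogram, h = cand)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
  n_big <- apply(cuts, 2, function(cl) sum(table(cl) >= min_module_size))
  if (max(n_big) == 0)
    return(stats::setNames(integer(length(dendrogram$order)),
                           dendrogram$labels))
  best <- max(which(n_big == max(n_big)))    # largest height among ties
  renumber_labels(cuts[, best], min_module_size)
}

# drop clusters below min size to 0 and renumber by decreasing size,
# ties by lexicographically smallest member gene
renumber_labels <- function(raw, min_module_size) {
  labels <- stats::setNames(integer(length(raw)), names(raw))
  sizes <- table(raw)
  keep <- setdiff(names(sizes)[sizes >= min_module_size], "0")
  if (length(keep)) {
    first_gene <- vapply(keep, function(cl) min(names(raw)[raw == cl]), "")
    ord <- keep[order(-sizes[keep], first_gene)]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  labels
}

#' Module eigengene (first principal component of a module)
#'
#' Member gene profiles are standardized (mean 0, sd 1 across samples) and
#' the first right-singular vector over samples — the direction of maximal
#' explained variance — is the eigengene, unit-norm and oriented to correlate
#' positively with the mean standardized member profile.
#'
#' @param expr An `expr_matrix` (log2(TPM+1)).
#' @param members Character vector of member gene ids (>= 1; zero-variance
#'   members are dropped with a warning).
#' @return Named numeric vector over samples, unit Euclidean norm.
#' @export
module_eigengene <- function(expr, members) {
  x <- expr$values[members, , drop = FALSE]
  if (ncol(x) < 2) abort("eigengene needs at least 2 samples")
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warn("excluding %d zero-variance member gene(s)", sum(v == 0))
    x <- x[v > 0, , drop = FALSE]
  }
  if (!nrow(x)) abort("no member gene with nonzero variance")
  xs <- t(scale(t(x)))
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  m <- colMeans(xs)
  orient <- sum(e * (m - mean(m)))
  if (orient == 0) orient <- sum(e)
  if (orient < 0) e <- -e
  stats::setNames(e, colnames(expr$values))
}

eigengene_matrix <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) abort("no assigned module")
  eg <- t(vapply(mods,
                 function(m) module_eigengene(expr, names(labels)[labels == m]),
                 numeric(ncol(expr$values))))
  rownames(eg) <- paste0("M", mods)
  eg
}

#' Merge closely related modules
#'
#' Iteratively computes module eigengenes and merges the most-correlated
#' pair whose eigengene correlation exceeds `threshold`, recomputing after
#' each merge, until no pair exceeds it. The module count strictly decreases
#' each iteration, so the procedure terminates. Output labels are renumbered
#' by decreasing size.
#'
#' @param expr An `expr_matrix` (log2(TPM+1)).
#' @param labels Named integer vector from [cut_tree()].
#' @param threshold Eigengene correlation above which modules merge
#'   (default 0.75).
#' @return Named integer vector of merged labels.
#' @export
merge_modules <- function(expr, labels, threshold = 0.75) {
  if (!any(labels > 0)) abort("no module to merge")
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    eg <- eigengene_matrix(expr, labels)
    cc <- stats::cor(t(eg))
    diag(cc) <- -Inf
    i <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[i[1], i[2]] <= threshold) break
    from <- mods[max(i)]; into <- mods[min(i)]
    labels[labels == from] <- into
  }
  renumber_labels(labels, min_module_size = 1)
}

#' Module membership (K_ME) and threshold-based assignment
#'
#' `K_ME` of gene g in module m is the Pearson correlation between g's
#' expression profile and m's eigengene. `assign_by_kme` grants membership
#' when `K_ME > threshold`; a gene may belong to several modules (or none).
#'
#' @param expr An `expr_matrix` (log2(TPM+1)).
#' @param eigengenes Modules x samples eigengene matrix.
#' @return `module_membership`: genes x modules matrix of correlations in
#'   \[-1, 1\].
#' @export
module_membership <- function(expr, eigengenes) {
  stats::cor(t(expr$values), t(eigengenes))
}

#' @rdname module_membership
#' @param kme Genes x modules K_ME matrix.
#' @param threshold Membership cutoff (default 0.75, strict).
#' @return `assign_by_kme`: named list module -> member gene ids (possibly
#'   overlapping).
#' @export
assign_by_kme <- function(kme, threshold = 0.75) {
  out <- lapply(colnames(kme), function(m)
    sort(rownames(kme)[kme[, m] > threshold]))
  stats::setNames(out, colnames(kme))
}

#' Module-trait correlation with Student-t p-values
#'
#' Correlates each module eigengene with each binary cell-type indicator and
#' reports the two-sided p-value of `t = r sqrt(n-2) / sqrt(1-r^2)` on n-2
#' degrees of freedom.
#'
#' @param eigengenes Modules x samples matrix.
#' @param traits A [trait_design()] whose samples match the eigengene
#'   columns.
#' @return A list with matrices `r` and `p` (modules x cell types).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  ind <- traits$indicator
  if (!identical(sort(colnames(eigengenes)), sort(rownames(ind))))
    abort("samples of eigengenes and traits do not match")
  ind <- ind[colnames(eigengenes), , drop = FALSE]
  n <- ncol(eigengenes)
  if (n < 3) abort("need at least 3 samples for module-trait correlation")
  r <- stats::cor(t(eigengenes), ind)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p)
}

#' Detect co-expression modules end to end
#'
#' Convenience wrapper running the whole network stage: soft-threshold
#' selection (unless a power is fixed in the config), signed-hybrid
#' adjacency, topological overlap, average-linkage clustering, tree cut,
#' eigengene-correlation merging, eigengenes, K_ME membership and
#' module-trait statistics.
#'
#' @param expr An `expr_matrix` of log2(TPM+1) values (typically restricted
#'   to a variance-selected gene set).
#' @param traits A [trait_design()] covering the samples.
#' @param config A [network_config()].
#' @return A list of class `module_set`: `labels`, `eigengenes`, `kme`,
#'   `membership_sets`, `trait_cor`, `trait_p`, `power`, `reached_target`,
#'   `fits`.
#' @export
detect_modules <- function(expr, traits, config = network_config()) {
  if (is.null(config$power)) {
    pick <- pick_soft_threshold(expr, config$candidate_powers,
                                config$target_scale_free_r2,
                                config$n_degree_bins)
    power <- pick$power; fits <- pick$fits; reached <- pick$reached_target
  } else {
    power <- config$power; fits <- NULL; reached <- NA
  }
  adj <- signed_hybrid_adjacency(expr, power)
  tom <- topological_overlap(adj)
  tree <- cluster_genes(tom)
  labels <- cut_tree(tree, config$min_module_size)
  if (any(labels > 0))
    labels <- merge_modules(expr, labels, config$merge_cor_threshold)
  # purify: a clustered gene that fails the K_ME membership rule for its own
  # module is left unassigned, so labels reflect coherent cores
  if (any(labels > 0)) {
    eg <- eigengene_matrix(expr, labels)
    kme0 <- module_membership(expr, eg)
    own <- kme0[cbind(names(labels)[labels > 0],
                      paste0("M", labels[labels > 0]))]
    labels[labels > 0][own <= config$kme_threshold] <- 0L
    labels <- renumber_labels(labels, config$min_module_size)
  }
  if (!any(labels > 0))
    abort("no module survived size and membership filtering")
  eg <- eigengene_matrix(expr, labels)
  kme <- module_membership(expr, eg)
  mt <- module_trait_correlation(eg, traits)
  structure(list(labels = labels, eigengenes = eg, kme = kme,
                 membership_sets = assign_by_kme(kme, config$kme_threshold),
                 trait_cor = mt$r, trait_p = mt$p,
                 power = power, reached_target = reached, fits = fits),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- max(x$labels)
  cat(sprintf("module_set: %d modules over %d genes (power %g), %d unassigned\n",
              n_mod, length(x$labels), x$power, sum(x$labels == 0)))
  invisible(x)
}
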
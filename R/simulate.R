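#' Configuration for the synthetic RNA-seq generator
#'
#' Describes a multi-cell-type bulk RNA-seq experiment with planted
#' structure: co-expression modules driven by latent per-sample activities,
#' cell-type-specific activity profiles, tissue-specific gene labels,
#' differentially expressed genes between a designated pair of cell types,
#' and per-gene lengths/sequencing depths for count generation.
#'
#' The default design mirrors a 6-cell-type experiment with 26 biological
#' replicates in total and 5 planted modules of 50 genes at a within-module
#' correlation of 0.81.
#'
#' @param n_genes Total number of genes.
#' @param n_cell_types Number of cell types.
#' @param replicates_per_type Integer vector of biological replicates per
#'   cell type (recycled if scalar). Default `c(5, 5, 4, 4, 4, 4)` (26 total).
#' @param module_sizes Integer vector; one planted module per entry. Their
#'   sum must not exceed `n_genes`.
#' @param within_module_cor Target pairwise Pearson correlation of the latent
#'   expression of module members, in (0, 1).
#' @param activity_profiles Modules x cell-types matrix of mean latent
#'   activity. Default: module m has mean 4 in cell type m, 0 elsewhere.
#' @param noise_sd Standard deviation of module-member latent noise. At the
#'   default 1, the mean pairwise latent correlation of module members equals
#'   `within_module_cor` exactly by construction.
#' @param loading_spread Half-width of the uniform distribution of member
#'   loadings around `sqrt(within_module_cor)`. Heterogeneous loadings give
#'   each module a hub-to-periphery connectivity gradient, as real
#'   co-expression modules have; the mean pairwise member correlation is
#'   unchanged. Set to 0 for identical loadings.
#' @param background_noise_sd Latent noise SD of background (non-module)
#'   genes. The default 0.5 makes background genes less variable across
#'   samples than module genes, whose activity shifts with cell type — the
#'   property that variance-based gene selection exploits in real data.
#' @param de_fraction Fraction of genes planted as differentially expressed
#'   between the two contrast cell types.
#' @param de_log2fc Magnitude of the planted log2 fold-change.
#' @param de_contrast Length-2 integer vector: indices of the two cell types
#'   contrasted (the shift is applied in the first). The default contrasts
#'   the last cell type — which drives no planted module under the default
#'   activity profiles — against the first, so planted DE structure does not
#'   masquerade as a planted module.
#' @param n_tissue_specific Number of tissue-specific genes planted per
#'   tissue (tissues are named after the cell types).
#' @param sequencing_depth Expected library size per sample.
#' @param gene_length_range Length-2 vector; gene lengths (bp) are drawn
#'   uniformly from this range.
#' @param seed Mandatory integer seed; generation is a pure function of the
#'   configuration including the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cell_types = 6,
                       replicates_per_type = c(5, 5, 4, 4, 4, 4),
                       module_sizes = rep(50, 5),
                       within_module_cor = 0.81,
                       activity_profiles = NULL,
                       noise_sd = 1,
                       loading_spread = 0.1,
                       background_noise_sd = 0.5,
                       de_fraction = 0.05,
                       de_log2fc = 2,
                       de_contrast = c(6, 1),
                       n_tissue_specific = 30,
                       sequencing_depth = 1e6,
                       gene_length_range = c(200, 10000),
                       seed) {
  if (missing(seed)) abort("'seed' is mandatory")
  assert_scalar_num(seed, "seed")
  if (length(replicates_per_type) == 1L)
    replicates_per_type <- rep(replicates_per_type, n_cell_types)
  if (length(replicates_per_type) != n_cell_types)
    abort("'replicates_per_type' must have one entry per cell type")
  n_modules <- length(module_sizes)
  if (sum(module_sizes) > n_genes)
    abort("sum of module sizes exceeds n_genes")
  if (!(within_module_cor > 0 && within_module_cor < 1))
    abort("'within_module_cor' must lie strictly inside (0, 1)")
  if (is.null(activity_profiles)) {
    activity_profiles <- matrix(0, n_modules, n_cell_types)
    for (m in seq_len(n_modules))
      activity_profiles[m, 1 + (m - 1) %% n_cell_types] <- 4
  }
  if (!is.matrix(activity_profiles) ||
      nrow(activity_profiles) != n_modules ||
      ncol(activity_profiles) != n_cell_types)
    abort("'activity_profiles' must be a modules x cell-types matrix")
  if (noise_sd < 0 || background_noise_sd < 0)
    abort("noise standard deviations must be non-negative")
  a_mean <- sqrt(within_module_cor)
  if (loading_spread < 0 || a_mean + loading_spread > 1 ||
      a_mean - loading_spread <= 0)
    abort("'loading_spread' must keep loadings inside (0, 1)")
  if (length(de_contrast) != 2 || any(de_contrast > n_cell_types))
    abort("'de_contrast' must index two cell types")
  if (n_tissue_specific * n_cell_types > n_genes)
    abort("too many tissue-specific genes for n_genes")
  structure(list(
    n_genes = n_genes, n_cell_types = n_cell_types,
    replicates_per_type = as.integer(replicates_per_type),
    module_sizes = as.integer(module_sizes),
    within_module_cor = within_module_cor,
    activity_profiles = activity_profiles,
    noise_sd = noise_sd,
    loading_spread = loading_spread,
    background_noise_sd = background_noise_sd,
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    de_contrast = as.integer(de_contrast),
    n_tissue_specific = as.integer(n_tissue_specific),
    sequencing_depth = sequencing_depth,
    gene_length_range = gene_length_range,
    seed = as.integer(seed)), class = "sim_config")
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

#' Simulate a count matrix with planted modules, DE genes and tissue labels
#'
#' For each module m and sample s of cell type t, a latent module activity
#' `e = activity_profiles[m, t] + N(0, 1)` is drawn; member gene g's latent
#' expression is `a_g * e + sqrt(1 - a_g^2) * N(0, noise_sd * s_m)` with
#' loading `a_g` drawn uniformly from `sqrt(within_module_cor) +-
#' loading_spread` and `s_m` the standard deviation of module m's activity
#' over the whole design (cell-type spread plus the unit per-sample noise).
#' Scaling the gene-level noise to the activity's own scale makes the
#' pairwise latent correlation of members `a_g * a_h` at `noise_sd = 1`
#' whatever the activity profile, so it averages `within_module_cor` while
#' connectivity varies smoothly from hub to peripheral members. Background genes are
#' independent noise with SD `background_noise_sd`. Counts are Poisson with rate proportional to
#' `depth * length_kb * softplus(latent)`, rescaled per sample so the
#' expected library size equals the configured depth. Genes planted as
#' differentially expressed receive a `2^log2fc` rate multiplier in the first
#' contrast cell type (alternating sign across the planted genes); they are
#' drawn from the background so module structure is untouched.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (`expr_matrix`, raw counts),
#'   `annotation` (`gene_annotation`), `traits` (`trait_design`) and `truth`
#'   (see Details). `truth` carries `module_labels` (named integer vector,
#'   0 = background), `activity` (modules x samples latent activities),
#'   `latent` (genes x samples latent expression), `de` (data.frame of
#'   planted genes and signed log2 fold-changes), `de_contrast` (cell-type
#'   names), `tissue_sets` (named list) and `bridge` (filled by
#'   [simulate_ppi()]).
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 200, module_sizes = c(30, 30),
#'                                       seed = 1))
#' sim$counts
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) abort("'config' must be a sim_config")
  withr::with_seed(config$seed, {
    n <- config$n_genes
    gid <- sprintf("G%05d", seq_len(n))
    ct <- sprintf("CT%d", seq_len(config$n_cell_types))
    type_of <- rep(ct, config$replicates_per_type)
    sid <- unlist(lapply(seq_along(ct), function(t)
      sprintf("%s_r%d", ct[t], seq_len(config$replicates_per_type[t]))))
    ns <- length(sid)

    # planted module labels: first sum(module_sizes) genes, consecutively
    labels <- stats::setNames(integer(n), gid)
    idx <- 0L
    for (m in seq_along(config$module_sizes)) {
      labels[idx + seq_len(config$module_sizes[m])] <- m
      idx <- idx + config$module_sizes[m]
    }

    # latent module activities per sample
    nm <- length(config$module_sizes)
    type_idx <- match(type_of, ct)
    activity <- config$activity_profiles[, type_idx, drop = FALSE] +
      matrix(stats::rnorm(nm * ns), nm, ns)
    dimnames(activity) <- list(paste0("M", seq_len(nm)), sid)

    # latent gene expression; per-gene loadings uniform around
    # sqrt(within_module_cor) so mean pairwise member correlation hits target
    a_mean <- sqrt(config$within_module_cor)
    loadings <- stats::setNames(rep(NA_real_, n), gid)
    latent <- matrix(stats::rnorm(n * ns, sd = config$background_noise_sd),
                     n, ns, dimnames = list(gid, sid))
    for (m in seq_len(nm)) {
      members <- which(labels == m)
      a <- stats::runif(length(members),
                        a_mean - config$loading_spread,
                        a_mean + config$loading_spread)
      loadings[members] <- a
      # activity scale over the design: cell-type spread + unit sample noise
      mu <- config$activity_profiles[m, type_idx]
      s_m <- sqrt(1 + mean((mu - mean(mu))^2))
      noise <- matrix(stats::rnorm(length(members) * ns,
                                   sd = config$noise_sd * s_m),
                      length(members), ns)
      latent[members, ] <- a * matrix(activity[m, ], length(members), ns,
                                      byrow = TRUE) +
        sqrt(1 - a^2) * noise
    }

    # planted DE genes among the background, alternating direction
    bg <- which(labels == 0L)
    n_de <- min(length(bg), floor(config$de_fraction * n))
    de_idx <- sort(sample(bg, n_de))
    de_sign <- rep_len(c(1, -1), n_de)
    de <- data.frame(gene_id = gid[de_idx],
                     log2_fold_change = de_sign * config$de_log2fc,
                     stringsAsFactors = FALSE)

    # gene lengths and tissue-specific labels
    len <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                  n, replace = TRUE)
    cats <- c("tissue_enriched", "group_enriched", "tissue_enhanced")
    spec_cat <- rep("none", n)
    spec_tis <- rep(list(character()), n)
    ts_pool <- sample(n)          # disjoint assignment across tissues
    tissue_sets <- list()
    for (t in seq_along(ct)) {
      take <- ts_pool[(t - 1) * config$n_tissue_specific +
                        seq_len(config$n_tissue_specific)]
      tissue_sets[[ct[t]]] <- sort(gid[take])
      spec_cat[take] <- cats[1 + (seq_along(take) - 1) %% 3]
      for (i in take) spec_tis[[i]] <- ct[t]
    }

    # Poisson counts: rate ~ depth * length_kb * softplus(latent), with the
    # planted fold-change applied in the first contrast cell type, then
    # rescaled so each library's expected size equals the configured depth
    expr_scale <- softplus(latent)
    mult <- 2^(de_sign * config$de_log2fc)
    in_a <- type_idx == config$de_contrast[1]
    expr_scale[de_idx, in_a] <- expr_scale[de_idx, in_a, drop = FALSE] * mult
    len_kb <- len / 1000
    rate <- expr_scale * len_kb
    rate <- sweep(rate, 2, colSums(rate), "/") * config$sequencing_depth
    counts <- matrix(stats::rpois(n * ns, rate), n, ns,
                     dimnames = list(gid, sid))

    indicator <- outer(type_of, ct, `==`) * 1
    dimnames(indicator) <- list(sid, ct)

    truth <- list(module_labels = labels, activity = activity,
                  latent = latent, loadings = loadings, de = de,
                  de_contrast = ct[config$de_contrast],
                  tissue_sets = tissue_sets, bridge = NULL)
    list(counts = expr_matrix(counts, "raw_counts"),
         annotation = gene_annotation(gid, len, spec_cat, spec_tis),
         traits = trait_design(indicator),
         truth = truth)
  })
}

#' Turn planted DE truth into a DE result table
#'
#' Stands in for an external differential-expression run on synthetic data:
#' planted genes get their true log2 fold-change and a vanishing adjusted
#' p-value; all other genes get 0 and 1.
#'
#' @param sim Output of [simulate_expression()] (or its `truth` element).
#' @param p_planted Adjusted p assigned to planted genes.
#' @return A [de_table()] over all simulated genes.
#' @export
truth_de_table <- function(sim, p_planted = 1e-6) {
  truth <- if (!is.null(sim$truth)) sim$truth else sim
  gid <- names(truth$module_labels)
  lfc <- stats::setNames(numeric(length(gid)), gid)
  lfc[truth$de$gene_id] <- truth$de$log2_fold_change
  p <- ifelse(gid %in% truth$de$gene_id, p_planted / 10, 1)
  padj <- ifelse(gid %in% truth$de$gene_id, p_planted, 1)
  de_table(gid, unname(lfc), p, padj)
}

#' Simulate a PPI graph with a known maximum-betweenness bridge
#'
#' Builds one dense community per requested size over the genes of the first
#' planted modules (a deterministic spanning path plus Erdos-Renyi extras at
#' probability `p_in`, all with scores at or above 0.7), joins them through a
#' single bridge gene (two edges into each community, so no community member
#' is itself a cut vertex and the bridge carries every cross-community
#' shortest path alone), and adds decoy edges
#' scored below 0.7 that a 0.7 threshold must discard. The bridge is the
#' first gene of the first module not used for a community (so it lies among
#' the co-expressed genes a network-wide PPI analysis sees), or the first
#' background gene if every module hosts a community. Every shortest path between different communities passes
#' through the bridge, which is recorded as the true bottleneck.
#'
#' @param sim Output of [simulate_expression()].
#' @param community_sizes Integer vector (length >= 2) of community sizes;
#'   each must be >= 3 and no larger than its source module.
#' @param p_in Probability of each non-path within-community edge.
#' @param n_decoys Number of sub-threshold decoy edges.
#' @param seed Integer seed.
#' @return A list with `edges` (a `ppi_edge_list`, unit-scale scores) and
#'   `truth` (the input truth with `bridge` and `communities` filled in).
#' @export
simulate_ppi <- function(sim, community_sizes = c(15, 15), p_in = 0.9,
                         n_decoys = 30, seed) {
  if (missing(seed)) abort("'seed' is mandatory")
  truth <- sim$truth
  labels <- truth$module_labels
  n_mod <- max(labels)
  if (n_mod < 2) abort("simulate_ppi needs at least 2 planted modules")
  if (length(community_sizes) < 2) abort("need at least 2 communities")
  if (any(community_sizes < 3)) abort("community sizes must be >= 3")
  if (length(community_sizes) > n_mod)
    abort("more communities than planted modules")
  gid <- names(labels)
  if (n_mod > length(community_sizes)) {
    bridge <- sort(gid[labels == length(community_sizes) + 1L])[1]
  } else {
    bg <- sort(gid[labels == 0L])
    if (!length(bg)) abort("no gene available as bridge")
    bridge <- bg[1]
  }

  withr::with_seed(as.integer(seed), {
    communities <- vector("list", length(community_sizes))
    a <- character(); b <- character(); s <- numeric()
    for (i in seq_along(community_sizes)) {
      members <- sort(gid[labels == i])
      if (length(members) < community_sizes[i])
        abort("module %d smaller than requested community size", i)
      members <- members[seq_len(community_sizes[i])]
      communities[[i]] <- members
      # spanning path guarantees connectivity
      a <- c(a, members[-length(members)]); b <- c(b, members[-1])
      # Erdos-Renyi extras among the remaining pairs
      prs <- utils::combn(members, 2)
      adjacent <- abs(match(prs[1, ], members) - match(prs[2, ], members)) == 1
      prs <- prs[, !adjacent, drop = FALSE]
      keep <- stats::runif(ncol(prs)) < p_in
      a <- c(a, prs[1, keep]); b <- c(b, prs[2, keep])
      # bridge attaches to the first two members of each community
      a <- c(a, bridge, bridge); b <- c(b, members[1], members[2])
    }
    s <- stats::runif(length(a), 0.7, 1)
    # decoy edges below the 0.7 threshold, between random distinct genes
    nodes <- c(bridge, unlist(communities))
    da <- sample(nodes, n_decoys, replace = TRUE)
    db <- sample(gid, n_decoys, replace = TRUE)
    ok <- da != db
    edges <- ppi_edge_list(c(a, da[ok]), c(b, db[ok]),
                           c(s, stats::runif(sum(ok), 0.3, 0.699)),
                           score_scale = "unit")
    truth$bridge <- bridge
    truth$communities <- communities
    list(edges = edges, truth = truth)
  })
}
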
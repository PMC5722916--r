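#' Configuration for an end-to-end pipeline run
#'
#' Collects the input objects (or paths), the stage parameters and the
#' output directory for [run_pipeline()]. Inputs may be given either as
#' in-memory objects from this package or as file paths in the formats of
#' the readers ([read_expression_matrix()] etc.).
#'
#' @param counts Count matrix (`expr_matrix` of raw counts, or TSV path).
#' @param annotation Gene annotation (`gene_annotation` or TSV path).
#' @param traits Traits design (`trait_design` or TSV path).
#' @param out_dir Directory where every intermediate and the manifest are
#'   written (created if missing).
#' @param seed Mandatory global seed; per-stage seeds are derived from it by
#'   fixed offsets so adding a stage never perturbs earlier stages.
#' @param replicate_groups Optional named vector mapping sample to
#'   technical-replicate group (summed before normalization).
#' @param de Optional DE table (`de_table` or TSV path) for the
#'   randomization stage.
#' @param gene_sets Optional gene-set collection (`gene_set_collection` or
#'   GMT path) for per-module enrichment.
#' @param ppi_edges Optional PPI edge list (`ppi_edge_list` or path; paths
#'   are read with `ppi_score_scale`).
#' @param ppi_score_scale Score scale used when `ppi_edges` is a path.
#' @param network A [network_config()].
#' @param tpm_threshold Expression filter cutoff (default 1, mean TPM,
#'   strict).
#' @param n_random Randomization draws per module (default 10000).
#' @param fc_threshold,padj_threshold DE up-regulation filter (defaults 2
#'   and 0.01).
#' @param ppi_weight_min,bottleneck_percentile PPI stage parameters
#'   (defaults 0.7 and 95).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, annotation, traits, out_dir, seed,
                            replicate_groups = NULL, de = NULL,
                            gene_sets = NULL, ppi_edges = NULL,
                            ppi_score_scale = "unit",
                            network = network_config(),
                            tpm_threshold = 1,
                            n_random = 10000,
                            fc_threshold = 2, padj_threshold = 0.01,
                            ppi_weight_min = 0.7,
                            bottleneck_percentile = 95) {
  if (missing(seed)) abort("'seed' is mandatory")
  assert_scalar_num(seed, "seed")
  structure(list(counts = counts, annotation = annotation, traits = traits,
                 out_dir = out_dir, seed = as.integer(seed),
                 replicate_groups = replicate_groups, de = de,
                 gene_sets = gene_sets, ppi_edges = ppi_edges,
                 ppi_score_scale = ppi_score_scale, network = network,
                 tpm_threshold = tpm_threshold, n_random = n_random,
                 fc_threshold = fc_threshold,
                 padj_threshold = padj_threshold,
                 ppi_weight_min = ppi_weight_min,
                 bottleneck_percentile = bottleneck_percentile),
            class = "pipeline_config")
}

resolve_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    abort("stage '%s' failed: %s", stage, conditionMessage(e)))
}

# serialize config deterministically for hashing (objects included by value)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dump <- config
  dump$out_dir <- NULL                 # path of the run, not of the analysis
  saveRDS(dump, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: technical-replicate combination (if groups are
#' given), TPM normalization, log transform, mean-TPM expression filter,
#' top-quartile variance selection, co-expression module detection
#' (soft-threshold pick, adjacency, TOM, clustering, tree cut, merging,
#' eigengenes, K_ME, module-trait statistics), and — when the corresponding
#' inputs are configured — per-module size-matched randomization tests
#' against the DE up-regulated set, per-module gene-set enrichment, and
#' per-module PPI bottleneck analysis. Every intermediate is persisted as a
#' TSV under `out_dir`, progress is logged to stderr with stage markers, and
#' a JSON manifest of md5 checksums is written at the end. Identical config
#' and seed yield byte-identical outputs and manifest.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    abort("'config' must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character()
  wh <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  out <- function(name) file.path(config$out_dir, name)
  files <- character()
  add <- function(path) files <<- c(files, path)

  counts <- run_stage("read_counts",
    resolve_input(config$counts, read_expression_matrix, unit = "raw_counts"))
  annotation <- run_stage("read_annotation",
    resolve_input(config$annotation, read_gene_annotation))
  traits <- run_stage("read_traits",
    resolve_input(config$traits, read_traits))

  if (!is.null(config$replicate_groups)) {
    counts <- run_stage("combine_replicates",
      combine_technical_replicates(counts, config$replicate_groups))
    stage_log("combine_replicates", "%d samples after combining",
              ncol(counts$values))
  }
  add(write_expression_matrix(counts, out("counts.tsv")))

  withCallingHandlers({
    tpm <- run_stage("tpm", compute_tpm(counts, annotation))
    add(write_expression_matrix(tpm, out("tpm.tsv")))
    logtpm <- run_stage("log_transform", log_transform(tpm))
    stage_log("tpm", "normalized %d genes x %d samples",
              nrow(tpm$values), ncol(tpm$values))

    expressed <- run_stage("filter_expressed",
      filter_expressed(tpm, config$tpm_threshold))
    stage_log("filter_expressed", "%d genes with mean TPM > %g",
              length(expressed$selected_gene_ids), config$tpm_threshold)
    top_var <- run_stage("top_quartile_variance",
      select_top_quartile_variance(logtpm, expressed$selected_gene_ids))
    stage_log("top_quartile_variance", "%d genes selected",
              length(top_var$selected_gene_ids))
    sel_df <- data.frame(
      gene_id = c(expressed$selected_gene_ids, top_var$selected_gene_ids),
      criterion = rep(c("tpm_gt1", "top_quartile_variance"),
                      c(length(expressed$selected_gene_ids),
                        length(top_var$selected_gene_ids))))
    utils::write.table(sel_df, out("selection.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add(out("selection.tsv"))

    net_expr <- expr_matrix(logtpm$values[top_var$selected_gene_ids, ,
                                          drop = FALSE], "log2_tpm_plus1")
    modules <- run_stage("network", detect_modules(net_expr, traits,
                                                   config$network))
    stage_log("network", "power %g, %d modules, %d genes unassigned",
              modules$power, max(modules$labels), sum(modules$labels == 0))

    utils::write.table(
      data.frame(gene_id = names(modules$labels), module = modules$labels),
      out("module_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    add(out("module_labels.tsv"))
    utils::write.table(
      data.frame(module = rownames(modules$eigengenes), modules$eigengenes,
                 check.names = FALSE),
      out("eigengenes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    add(out("eigengenes.tsv"))
    utils::write.table(
      data.frame(gene_id = rownames(modules$kme), modules$kme,
                 check.names = FALSE),
      out("kme.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    add(out("kme.tsv"))
    mt <- data.frame(module = rownames(modules$trait_cor),
                     modules$trait_cor, check.names = FALSE)
    for (ct in colnames(modules$trait_p))
      mt[[paste0("p_", ct)]] <- modules$trait_p[, ct]
    utils::write.table(mt, out("module_trait.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add(out("module_trait.tsv"))
    if (!is.null(modules$fits)) {
      utils::write.table(modules$fits, out("soft_threshold.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add(out("soft_threshold.tsv"))
    }

    module_ids <- seq_len(max(modules$labels))
    module_genes <- lapply(module_ids, function(m)
      sort(names(modules$labels)[modules$labels == m]))

    if (!is.null(config$de)) {
      de <- run_stage("read_de", resolve_input(config$de, read_de_table))
      up <- run_stage("upregulated",
        upregulated_sets(de, config$fc_threshold, config$padj_threshold))
      universe <- gene_ids(counts)
      rnd <- lapply(seq_along(module_ids), function(i) {
        res <- randomization_module_test(
          module_genes[[i]], intersect(up$up_in_a, universe), universe,
          n_random = config$n_random,
          seed = derive_seed(config$seed, 100 + i))
        data.frame(module = paste0("M", module_ids[i]),
                   observed = res$observed, p_value = res$p_value,
                   n_random = res$n_random)
      })
      rnd <- do.call(rbind, rnd)
      utils::write.table(rnd, out("randomization.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add(out("randomization.tsv"))
      stage_log("randomization", "%d modules tested against %d up-regulated genes",
                nrow(rnd), length(up$up_in_a))
    }

    if (!is.null(config$gene_sets)) {
      gs <- run_stage("read_gene_sets",
        resolve_input(config$gene_sets, read_gmt))
      enr <- lapply(seq_along(module_ids), function(i) {
        q <- intersect(module_genes[[i]], gs$universe)
        if (!length(q)) return(NULL)
        res <- gene_set_enrichment(q, gs)
        cbind(module = paste0("M", module_ids[i]), res)
      })
      enr <- do.call(rbind, enr)
      utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add(out("enrichment.tsv"))
      stage_log("enrichment", "%d module x set tests", nrow(enr))
    }

    if (!is.null(config$ppi_edges)) {
      edges <- run_stage("read_ppi",
        resolve_input(config$ppi_edges, read_ppi_edges,
                      score_scale = config$ppi_score_scale))
      # network-wide analysis over all co-expressed (module) genes, plus one
      # view per module
      sets <- c(list(network = sort(unique(unlist(module_genes)))),
                stats::setNames(module_genes, paste0("M", module_ids)))
      ppi <- lapply(names(sets), function(nm) {
        res <- run_stage("ppi", analyze_ppi(edges, sets[[nm]],
                                            config$ppi_weight_min,
                                            config$bottleneck_percentile))
        cbind(module = nm, res)
      })
      ppi <- do.call(rbind, ppi)
      utils::write.table(ppi, out("ppi_bottlenecks.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add(out("ppi_bottlenecks.tsv"))
      stage_log("ppi", "%d bottleneck calls", sum(ppi$is_bottleneck))
    }
  }, warning = wh)

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("coexppi")),
    checksums = as.list(tools::md5sum(files)),
    warnings = warnings_seen)
  names(manifest$checksums) <- basename(files)
  # written atomically: rename only after the full JSON is on disk
  tmp <- paste0(out("manifest.json"), ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, out("manifest.json"))
  stage_log("manifest", "written to %s", out("manifest.json"))
  invisible(manifest)
}
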
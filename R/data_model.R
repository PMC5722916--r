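#' Expression matrix with a declared unit
#'
#' A light container for a dense genes x samples grid, in the style of
#' limma's expression classes: a numeric matrix with gene identifiers as row
#' names and sample identifiers as column names, plus a `unit` attribute that
#' records what the numbers are. Downstream operations check the unit, so
#' raw counts cannot silently be treated as TPM (or vice versa).
#'
#' @param values Numeric matrix, genes in rows (row names = gene ids),
#'   samples in columns (column names = sample ids).
#' @param unit One of `"raw_counts"`, `"tpm"`, `"log2_tpm_plus1"`.
#'   Raw counts must be non-negative integers; TPM must be non-negative.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- matrix(c(5, 7, 0, 3), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expr_matrix(m, "raw_counts")
#' @export
expr_matrix <- function(values, unit = c("raw_counts", "tpm", "log2_tpm_plus1")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    abort("'values' must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    abort("'values' must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(gid))
    abort("duplicate gene ids: %s",
          paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    abort("duplicate sample ids: %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values))
    abort("missing expression values are not supported")
  if (unit == "raw_counts") {
    if (any(values < 0) || any(values != round(values)))
      abort("raw counts must be non-negative integers")
  } else if (unit == "tpm") {
    if (any(values < 0)) abort("tpm values must be non-negative")
  }
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Gene annotation table
#'
#' Per-gene annotation: effective length (bp, used for TPM), and an optional
#' tissue-specificity call following the protein-atlas scheme, where a gene
#' may be "tissue enriched", "group enriched" or "tissue enhanced" in one or
#' more tissues.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param length_bp Positive integer effective lengths, one per gene.
#' @param specificity_category One of `"tissue_enriched"`, `"group_enriched"`,
#'   `"tissue_enhanced"`, `"none"` per gene (default all `"none"`).
#' @param specific_tissues List of character vectors, one per gene: the
#'   tissues the gene is specific to. Must be empty iff the category is
#'   `"none"`.
#' @return A `data.frame` of class `gene_annotation` with a `specific_tissues`
#'   list-column.
#' @export
gene_annotation <- function(gene_id, length_bp,
                            specificity_category = NULL,
                            specific_tissues = NULL) {
  assert_character(gene_id, "gene_id")
  if (anyDuplicated(gene_id))
    abort("duplicate gene ids in annotation")
  if (length(length_bp) != length(gene_id))
    abort("'length_bp' must have one entry per gene")
  if (anyNA(length_bp) || any(length_bp < 1) || any(length_bp != round(length_bp)))
    abort("'length_bp' must be positive integers")
  n <- length(gene_id)
  if (is.null(specificity_category)) specificity_category <- rep("none", n)
  valid <- c("tissue_enriched", "group_enriched", "tissue_enhanced", "none")
  if (!all(specificity_category %in% valid))
    abort("invalid specificity_category; must be one of %s",
          paste(valid, collapse = ", "))
  if (is.null(specific_tissues)) specific_tissues <- rep(list(character()), n)
  if (!is.list(specific_tissues) || length(specific_tissues) != n)
    abort("'specific_tissues' must be a list with one entry per gene")
  n_tis <- lengths(specific_tissues)
  bad <- (specificity_category == "none") != (n_tis == 0L)
  if (any(bad))
    abort("specific_tissues must be non-empty exactly when a specificity category is set (genes: %s)",
          paste(utils::head(gene_id[bad], 5), collapse = ", "))
  out <- data.frame(gene_id = gene_id,
                    length_bp = as.integer(length_bp),
                    specificity_category = specificity_category,
                    stringsAsFactors = FALSE)
  out$specific_tissues <- specific_tissues
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Binary sample-by-cell-type design ("traits file")
#'
#' Rows are samples, columns are cell types; each sample belongs to exactly
#' one cell type (exactly one 1 per row).
#'
#' @param indicator Binary numeric matrix, samples x cell types, with sample
#'   ids as rownames and cell-type names as colnames.
#' @return An object of class `trait_design`.
#' @export
trait_design <- function(indicator) {
  if (!is.matrix(indicator) || is.null(rownames(indicator)) ||
      is.null(colnames(indicator)))
    abort("'indicator' must be a matrix with sample rownames and cell-type colnames")
  if (anyDuplicated(rownames(indicator)) || anyDuplicated(colnames(indicator)))
    abort("duplicate sample or cell-type names in traits")
  if (!all(indicator %in% c(0, 1)))
    abort("traits indicator must be binary (0/1)")
  if (!all(rowSums(indicator) == 1))
    abort("each sample must belong to exactly one cell type")
  structure(list(indicator = indicator), class = "trait_design")
}

#' @export
print.trait_design <- function(x, ...) {
  cat(sprintf("trait_design: %d samples x %d cell types\n",
              nrow(x$indicator), ncol(x$indicator)))
  invisible(x)
}

#' Cell type of each sample in a trait design
#' @param traits A `trait_design`.
#' @return Named character vector: sample id -> cell-type name.
#' @export
cell_type_of <- function(traits) {
  ind <- traits$indicator
  stats::setNames(colnames(ind)[max.col(ind)], rownames(ind))
}

#' Named gene-set collection over a declared universe
#'
#' @param sets Named list of character vectors (the gene sets).
#' @param universe Character vector of gene ids; every set must be a subset.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  assert_character(universe, "universe")
  if (anyDuplicated(universe)) abort("duplicate ids in universe")
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    abort("'sets' must be a list with unique non-empty names")
  sets <- lapply(sets, unique)
  outside <- vapply(sets, function(s) any(!s %in% universe), logical(1))
  if (any(outside))
    abort("gene sets not contained in the universe: %s",
          paste(names(sets)[outside], collapse = ", "))
  structure(list(universe = universe, sets = sets),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Differential-expression result table
#'
#' One row per gene with log2 fold-change and raw/adjusted p-values, as
#' produced by standard DE tools.
#'
#' @param gene_id,log2_fold_change,p_value,p_adjusted Parallel vectors.
#' @return A `data.frame` of class `de_table`.
#' @export
de_table <- function(gene_id, log2_fold_change, p_value, p_adjusted) {
  assert_character(gene_id, "gene_id")
  if (anyDuplicated(gene_id)) abort("duplicate genes in DE table")
  n <- length(gene_id)
  if (length(log2_fold_change) != n || length(p_value) != n ||
      length(p_adjusted) != n)
    abort("DE table columns must have equal length")
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE) ||
      any(p_adjusted < 0 | p_adjusted > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  out <- data.frame(gene_id = gene_id,
                    log2_fold_change = as.numeric(log2_fold_change),
                    p_value = as.numeric(p_value),
                    p_adjusted = as.numeric(p_adjusted),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Combine technical replicates by summing raw counts
#'
#' Columns belonging to the same replicate group are added together, the
#' standard treatment of technical (library-level) replicates before
#' normalization. Output column order follows first occurrence of each group
#' in the input.
#'
#' @param x An `expr_matrix` with unit `"raw_counts"`.
#' @param grouping Named character vector mapping every sample id of `x` to a
#'   replicate-group name.
#' @return An `expr_matrix` of raw counts with one column per group.
#' @examples
#' m <- matrix(c(5, 7, 0, 1, 1, 1, 2, 0, 4), 3, 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
#' x <- expr_matrix(m, "raw_counts")
#' g <- c(s1 = "A", s2 = "A", s3 = "B")
#' combine_technical_replicates(x, g)$values
#' @export
combine_technical_replicates <- function(x, grouping) {
  if (!inherits(x, "expr_matrix")) abort("'x' must be an expr_matrix")
  if (x$unit != "raw_counts")
    abort("technical replicates can only be combined on raw counts (unit is '%s'); summing normalized values is undefined",
          x$unit)
  sid <- sample_ids(x)
  if (is.null(names(grouping)) || !all(sid %in% names(grouping)))
    abort("'grouping' must name a replicate group for every sample")
  grp <- grouping[sid]
  groups <- unique(unname(grp))         # first-occurrence order
  vals <- vapply(groups,
                 function(g) rowSums(x$values[, grp == g, drop = FALSE]),
                 numeric(nrow(x$values)))
  if (nrow(x$values) == 1L) vals <- matrix(vals, nrow = 1L)
  dimnames(vals) <- list(gene_ids(x), groups)
  expr_matrix(vals, "raw_counts")
}
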
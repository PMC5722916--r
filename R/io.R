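# Readers/writers for the plain-text formats the pipeline consumes and
# emits: TSV expression/traits/DE/annotation tables, GMT gene sets, and
# STRING-style 3-column edge lists. All tabular readers take an explicit
# delimiter and comment character.

read_table_checked <- function(path, sep = "\t", comment_char = "") {
  if (!file.exists(path)) abort("file not found: %s", path)
  utils::read.delim(path, sep = sep, comment.char = comment_char,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

# convert character columns to numeric, reporting the first offending cell
# with 1-based data coordinates (excluding the header)
numeric_cols <- function(df, path, id_col = 1L) {
  out <- df
  for (j in setdiff(seq_along(df), id_col)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      abort("non-numeric value '%s' in %s at row %d, column '%s'",
            df[[j]][bad[1]], path, bad[1], colnames(df)[j])
    out[[j]] <- v
  }
  out
}

#' Read / write a genes x samples expression matrix (TSV)
#'
#' The expected layout is a header row of sample ids and a first column of
#' gene ids; the remaining cells are numeric. Integer counts round-trip
#' loss-free.
#'
#' @param path File path.
#' @param unit Declared unit of the values (see [expr_matrix()]).
#' @param sep Field delimiter (default tab).
#' @param comment_char Comment character passed to the parser ("" disables).
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(path, unit = "raw_counts", sep = "\t",
                                   comment_char = "") {
  df <- read_table_checked(path, sep, comment_char)
  if (ncol(df) < 2) abort("expression TSV needs a gene-id column plus samples")
  gid <- df[[1]]
  if (anyDuplicated(gid))
    abort("duplicate gene id in %s: %s", path,
          paste(unique(gid[duplicated(gid)]), collapse = ", "))
  df <- numeric_cols(df, path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- gid
  expr_matrix(vals, unit)
}

#' @rdname read_expression_matrix
#' @param x An `expr_matrix` to write.
#' @export
write_expression_matrix <- function(x, path, sep = "\t") {
  if (!inherits(x, "expr_matrix")) abort("'x' must be an expr_matrix")
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a binary traits design (TSV)
#'
#' First column sample ids, remaining columns one 0/1 indicator per cell
#' type; every sample carries exactly one 1.
#'
#' @inheritParams read_expression_matrix
#' @return A `trait_design`.
#' @export
read_traits <- function(path, sep = "\t", comment_char = "") {
  df <- read_table_checked(path, sep, comment_char)
  if (ncol(df) < 2) abort("traits TSV needs a sample-id column plus cell types")
  sid <- df[[1]]
  df <- numeric_cols(df, path)
  ind <- as.matrix(df[, -1, drop = FALSE])
  rownames(ind) <- sid
  trait_design(ind)
}

#' @rdname read_traits
#' @param traits A `trait_design` to write.
#' @export
write_traits <- function(traits, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(traits$indicator), traits$indicator,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene annotation (TSV)
#'
#' Columns: `gene_id`, `length_bp`, `specificity_category`,
#' `specific_tissues` (semicolon-separated, empty when the category is
#' `none`).
#'
#' @inheritParams read_expression_matrix
#' @return A `gene_annotation`.
#' @export
read_gene_annotation <- function(path, sep = "\t", comment_char = "") {
  df <- read_table_checked(path, sep, comment_char)
  need <- c("gene_id", "length_bp", "specificity_category", "specific_tissues")
  if (!all(need %in% colnames(df)))
    abort("annotation TSV must have columns: %s", paste(need, collapse = ", "))
  len <- suppressWarnings(as.numeric(df$length_bp))
  if (anyNA(len)) abort("non-numeric gene length in %s", path)
  tis <- strsplit(df$specific_tissues, ";", fixed = TRUE)
  tis <- lapply(tis, function(v) v[nzchar(v)])
  gene_annotation(df$gene_id, len, df$specificity_category, tis)
}

#' @rdname read_gene_annotation
#' @param annotation A `gene_annotation` to write.
#' @export
write_gene_annotation <- function(annotation, path, sep = "\t") {
  df <- data.frame(
    gene_id = annotation$gene_id,
    length_bp = annotation$length_bp,
    specificity_category = annotation$specificity_category,
    specific_tissues = vapply(annotation$specific_tissues,
                              paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a differential-expression table (TSV)
#'
#' Columns: `gene_id`, `log2_fold_change`, `p_value`, `p_adjusted`.
#'
#' @inheritParams read_expression_matrix
#' @return A `de_table`.
#' @export
read_de_table <- function(path, sep = "\t", comment_char = "") {
  df <- read_table_checked(path, sep, comment_char)
  need <- c("gene_id", "log2_fold_change", "p_value", "p_adjusted")
  if (!all(need %in% colnames(df)))
    abort("DE TSV must have columns: %s", paste(need, collapse = ", "))
  df <- numeric_cols(df[need], path)
  de_table(df$gene_id, df$log2_fold_change, df$p_value, df$p_adjusted)
}

#' @rdname read_de_table
#' @param de A `de_table` to write.
#' @export
write_de_table <- function(de, path, sep = "\t") {
  utils::write.table(as.data.frame(de), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields `name`,
#' `description`, then member genes. On reading, the universe defaults to
#' the union of all members unless supplied.
#'
#' @param path File path.
#' @param universe Optional explicit universe; defaults to the union of
#'   members.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    abort("GMT line %d has fewer than 3 fields", short[1])
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) abort("duplicate set names in %s", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  gene_set_collection(sets, universe)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection` to write.
#' @param descriptions Optional named character vector of set descriptions
#'   (defaults to `"na"`).
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  nm <- names(collection$sets)
  desc <- if (is.null(descriptions)) stats::setNames(rep("na", length(nm)), nm)
          else descriptions
  lines <- vapply(nm, function(n) {
    paste(c(n, desc[[n]], collection$sets[[n]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-style protein-protein-interaction edge list
#'
#' Whitespace- or tab-delimited records `protein_a protein_b score`. Scores
#' are normalized to \[0, 1\]: STRING flat files carry integer combined
#' scores on a 0-1000 scale (divided by 1000 here), while pre-normalized
#' files declare `score_scale = "unit"`. Self-edges are dropped (with a
#' message of how many), and duplicate records of the same unordered pair
#' keep the maximum score.
#'
#' @param path File path.
#' @param score_scale `"string"` (0-1000) or `"unit"` (0-1).
#' @param comment_char Lines starting with this character are skipped.
#' @return A `data.frame` of class `ppi_edge_list` with columns `protein_a`,
#'   `protein_b`, `combined_score` (unit scale), at most one row per
#'   unordered pair.
#' @export
read_ppi_edges <- function(path, score_scale = c("string", "unit"),
                           comment_char = "#") {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.table(path, header = FALSE, comment.char = comment_char,
                          stringsAsFactors = FALSE,
                          col.names = c("protein_a", "protein_b", "score"))
  ppi_edge_list(df$protein_a, df$protein_b, df$score, score_scale)
}

#' @rdname read_ppi_edges
#' @param protein_a,protein_b Character vectors of interacting proteins.
#' @param score Numeric scores on the declared scale.
#' @export
ppi_edge_list <- function(protein_a, protein_b, score,
                          score_scale = c("string", "unit")) {
  score_scale <- match.arg(score_scale)
  if (!is.numeric(score) || anyNA(score)) abort("scores must be numeric")
  hi <- if (score_scale == "string") 1000 else 1
  if (any(score < 0 | score > hi))
    abort("score outside the declared '%s' scale [0, %s]", score_scale, hi)
  score <- if (score_scale == "string") score / 1000 else score
  self <- protein_a == protein_b
  if (any(self))
    message(sprintf("read_ppi_edges: dropped %d self-edge(s)", sum(self)))
  a <- protein_a[!self]; b <- protein_b[!self]; s <- score[!self]
  lo <- pmin(a, b); hi2 <- pmax(a, b)          # canonical unordered pair
  key <- paste(lo, hi2, sep = "\r")
  if (length(key)) {
    s <- vapply(split(s, key), max, 0)
    pairs <- do.call(rbind, strsplit(names(s), "\r", fixed = TRUE))
    out <- data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
                      combined_score = unname(s), stringsAsFactors = FALSE)
    out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(protein_a = character(), protein_b = character(),
                      combined_score = numeric(), stringsAsFactors = FALSE)
  }
  class(out) <- c("ppi_edge_list", "data.frame")
  out
}

#' @rdname read_ppi_edges
#' @param edges A `ppi_edge_list` to write (unit-scale scores).
#' @export
write_ppi_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
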
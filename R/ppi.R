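# PPI stage: threshold a STRING-style edge list to a module's genes, take
# the largest connected component, score nodes by shortest-path betweenness
# and call the top-5% as bottlenecks.

#' Build a thresholded PPI graph over a gene set
#'
#' Keeps edges whose combined score is at least `weight_min` (inclusive, the
#' standard high-confidence STRING cutoff of 0.7 by default) and whose both
#' endpoints belong to `genes` (typically a co-expression module). The
#' result is a simple, unweighted, undirected graph whose vertex set is the
#' supplied genes.
#'
#' @param edges A `ppi_edge_list` (unit-scale scores, see
#'   [read_ppi_edges()]).
#' @param genes Non-empty character vector of gene ids.
#' @param weight_min Minimum combined score (default 0.7).
#' @return An [igraph][igraph::igraph-package] graph.
#' @export
build_ppi_graph <- function(edges, genes, weight_min = 0.7) {
  if (!length(genes)) abort("empty gene set")
  genes <- sort(unique(genes))
  keep <- edges$combined_score >= weight_min &
    edges$protein_a %in% genes & edges$protein_b %in% genes
  g <- igraph::graph_from_data_frame(
    edges[keep, c("protein_a", "protein_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE))
  igraph::simplify(g)
}

#' Largest connected component of a PPI graph
#'
#' Returns the node-induced subgraph on the largest component; ties are
#' broken by the component containing the lexicographically smallest node.
#' An edgeless graph yields a single-node graph (smallest id) with a
#' warning.
#'
#' @param graph An igraph graph.
#' @return An igraph subgraph.
#' @export
largest_connected_component <- function(graph) {
  if (igraph::vcount(graph) == 0) abort("empty graph")
  if (igraph::ecount(graph) == 0) {
    warn("graph has no edges; returning the single lexicographically smallest node")
    return(igraph::induced_subgraph(
      graph, min(igraph::V(graph)$name)))
  }
  comp <- igraph::components(graph)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    smallest <- vapply(big, function(ci)
      min(igraph::V(graph)$name[comp$membership == ci]), "")
    big <- big[order(smallest)][1]
  }
  igraph::induced_subgraph(graph, comp$membership == big)
}

#' Shortest-path betweenness centrality
#'
#' Unnormalized betweenness on the undirected, unweighted graph: each node
#' v accrues, over every unordered pair (s, t) with v outside it, the
#' fraction of shortest s-t paths passing through v.
#'
#' @param graph An igraph graph (apply after
#'   [largest_connected_component()]).
#' @return Named numeric vector of scores (>= 0).
#' @export
betweenness_scores <- function(graph) {
  igraph::betweenness(graph, directed = FALSE, weights = NA, normalized = FALSE)
}

#' Call bottleneck genes from betweenness scores
#'
#' Bottlenecks are the nodes whose betweenness is at or above the 95th
#' percentile of the network's scores (ties at the threshold all included,
#' so the set can exceed 5% of nodes; with all scores equal, every node is a
#' bottleneck). The percentile uses R's default quantile definition; since
#' percentiles are invariant to monotone rescaling, normalizing betweenness
#' first would not change the called set.
#'
#' @param scores Named numeric vector from [betweenness_scores()].
#' @param percentile Percentile threshold (default 95).
#' @return Sorted character vector of bottleneck gene ids.
#' @export
call_bottlenecks <- function(scores, percentile = 95) {
  if (!length(scores)) abort("no scores")
  thr <- stats::quantile(scores, percentile / 100, names = FALSE)
  sort(names(scores)[scores >= thr])
}

#' PPI bottleneck analysis of one gene set
#'
#' Convenience wrapper: threshold the edge list to the gene set, extract the
#' largest connected component, compute betweenness and call bottlenecks.
#'
#' @inheritParams build_ppi_graph
#' @param percentile Bottleneck percentile (default 95).
#' @return A data.frame (one row per node of the analyzed component) with
#'   `gene_id`, `betweenness`, `is_bottleneck`, sorted by decreasing
#'   betweenness.
#' @export
analyze_ppi <- function(edges, genes, weight_min = 0.7, percentile = 95) {
  g <- build_ppi_graph(edges, genes, weight_min)
  lcc <- largest_connected_component(g)
  b <- betweenness_scores(lcc)
  bn <- call_bottlenecks(b, percentile)
  out <- data.frame(gene_id = names(b), betweenness = unname(b),
                    is_bottleneck = names(b) %in% bn,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$betweenness, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
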
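#' Build the signature-restricted interaction graph
#'
#' Keeps only edges whose two endpoints are both signature genes and
#' returns the induced undirected graph. Signature genes touching no
#' retained edge are dropped (isolated nodes carry no degree or
#' betweenness information).
#'
#' @param edges a data.frame of score-filtered edges, as from
#'   \code{\link{read_edge_list}} or \code{\link{simulate_ppi}}.
#' @param signature a \code{gene_signature} or character vector of gene
#'   symbols.
#' @return An \code{\link[igraph]{igraph}} undirected graph with a
#'   \code{combined_score} edge attribute.
#' @export
build_graph <- function(edges, signature) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b", "combined_score") %in% names(edges)))
  genes <- signature_genes(signature)
  keep <- edges$node_a %in% genes & edges$node_b %in% genes
  kept <- edges[keep, , drop = FALSE]
  if (!nrow(kept)) {
    warning("no interaction edge connects two signature genes; empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  igraph::graph_from_data_frame(
    data.frame(from = kept$node_a, to = kept$node_b,
               combined_score = kept$combined_score),
    directed = FALSE)
}

#' Normalized shortest-path betweenness centrality
#'
#' Unweighted shortest-path betweenness (endpoints excluded), computed per
#' connected component and normalized by (n - 1)(n - 2) / 2 where n is the
#' number of nodes in the graph, so a node lying on every shortest path of
#' a path or star graph scores 1. Interaction scores gate edge existence
#' upstream and play no role in path lengths.
#'
#' @param graph an undirected \code{igraph} graph.
#' @return Named numeric vector of betweenness values in [0, 1].
#' @export
betweenness_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) return(setNames(numeric(0), character(0)))
  raw <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  denom <- (n - 1) * (n - 2) / 2
  out <- if (denom > 0) raw / denom else raw * 0
  setNames(as.numeric(out), igraph::V(graph)$name)
}

#' Per-node degree and betweenness table
#'
#' @param graph an undirected \code{igraph} graph.
#' @return A data.frame with columns \code{gene}, \code{degree},
#'   \code{betweenness}, in node order.
#' @export
node_metrics <- function(graph) {
  if (igraph::vcount(graph) == 0)
    return(data.frame(gene = character(), degree = integer(),
                      betweenness = numeric(), stringsAsFactors = FALSE))
  data.frame(gene = igraph::V(graph)$name,
             degree = as.integer(igraph::degree(graph)),
             betweenness = unname(betweenness_centrality(graph)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank hub genes by connectivity degree
#'
#' Hubs are nodes with degree strictly above \code{min_degree}, ranked by
#' degree descending with ties broken by betweenness descending and then
#' gene symbol. Degree is the sole hard filter; betweenness is reported
#' and used only for ordering.
#'
#' @param graph an undirected \code{igraph} graph (or a
#'   \code{\link{node_metrics}} data.frame).
#' @param min_degree hub threshold; nodes with degree > \code{min_degree}
#'   are kept (default 5).
#' @return A data.frame \code{(gene, degree, betweenness)} of hubs,
#'   highest degree first.
#' @export
select_hubs <- function(graph, min_degree = 5) {
  metrics <- if (is.data.frame(graph)) graph else node_metrics(graph)
  stopifnot(all(c("gene", "degree", "betweenness") %in% names(metrics)))
  hubs <- metrics[metrics$degree > min_degree, , drop = FALSE]
  hubs <- hubs[order(-hubs$degree, -hubs$betweenness, hubs$gene), ,
               drop = FALSE]
  rownames(hubs) <- NULL
  hubs
}
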
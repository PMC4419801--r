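#' Build an interaction network from an edge list
#'
#' Creates a simple undirected graph: duplicate edges (in either
#' orientation) and self-loops are dropped, and an optional exclusion list
#' removes genes (and their incident edges) before any centrality is
#' computed — the standard way to discard identifiers without annotation
#' or extreme-degree outliers such as Ubiquitin C.
#'
#' @param edge_list two-column matrix/data.frame of gene-ID pairs.
#' @param exclusions character vector of gene IDs to remove (default none).
#' @return an `igraph` object; attributes `n_dropped_loops`,
#'   `n_dropped_duplicates` and `excluded` record the clean-up.
#' @export
build_network <- function(edge_list, exclusions = character()) {
  el <- as.matrix(edge_list)[, 1:2, drop = FALSE]
  mode(el) <- "character"
  if (nrow(el) == 0) stop("empty edge list")
  g0 <- igraph::graph_from_edgelist(el, directed = FALSE)
  loops <- sum(igraph::which_loop(g0))
  g <- igraph::simplify(g0)
  dups <- igraph::ecount(g0) - loops - igraph::ecount(g)
  if (length(exclusions))
    g <- igraph::delete_vertices(g, intersect(exclusions,
                                              igraph::V(g)$name))
  if (igraph::ecount(g) == 0 && igraph::vcount(g) == 0)
    stop("no edges or nodes left after filtering")
  g$n_dropped_loops <- loops
  g$n_dropped_duplicates <- dups
  g$excluded <- exclusions
  g
}

#' Degree, betweenness and closeness centralities
#'
#' Computes the three node centralities used throughout the package, on
#' unweighted shortest paths: degree (number of interaction partners),
#' betweenness (unnormalized, endpoint-excluded: for each unordered pair
#' of other nodes, the fraction of shortest paths passing through the
#' node), and closeness as the inverse mean shortest-path distance
#' restricted to the node's connected component (in (0, 1], 1 for a node
#' adjacent to every reachable node; isolated nodes get 0 by convention).
#'
#' @param network an `igraph` graph from [build_network()] or
#'   [generate_pin()].
#' @return data.frame with `gene`, `degree`, `betweenness`, `closeness`
#'   and `component_size` (documenting the component restriction).
#' @export
compute_centralities <- function(network) {
  stopifnot(igraph::is_igraph(network))
  if (igraph::vcount(network) == 0) stop("empty network")
  deg <- igraph::degree(network)
  btw <- igraph::betweenness(network, directed = FALSE, normalized = FALSE)
  cls <- suppressWarnings(igraph::closeness(network, normalized = TRUE))
  cls[!is.finite(cls)] <- 0  # isolated vertices
  comp <- igraph::components(network)
  nm <- igraph::V(network)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(network)))
  data.frame(gene = nm, degree = as.integer(deg), betweenness = btw,
             closeness = cls,
             component_size = comp$csize[comp$membership],
             row.names = NULL)
}

#' Generate a synthetic scale-free interaction network
#'
#' Barabasi-Albert preferential attachment: each new gene attaches to
#' `edges_per_new_node` existing genes with probability proportional to
#' their degree, yielding the connected, heavy-tailed degree distribution
#' characteristic of protein-interaction networks.
#'
#' @param n_genes number of genes (> `edges_per_new_node`).
#' @param edges_per_new_node edges added per new gene (>= 1).
#' @param seed integer seed (`NULL`: current RNG).
#' @return an `igraph` graph with vertex names `gene_00001`, ...
#' @export
generate_pin <- function(n_genes, edges_per_new_node = 3, seed = NULL) {
  stopifnot(n_genes > edges_per_new_node, edges_per_new_node >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(n_genes, m = edges_per_new_node,
                         directed = FALSE)
  igraph::V(g)$name <- sprintf("gene_%05d", seq_len(n_genes))
  g
}

#' Assign sweep status to genes as a function of their degree
#'
#' Bernoulli ground-truth assignment with a logit-linear coupling to
#' standardized degree: `logit(p) = logit(base_rate) +
#' coupling_effect * z(degree)`. A zero coupling makes sweep status
#' exchangeable across genes; positive coupling concentrates sweeps on
#' hubs, negative coupling on peripheral genes.
#'
#' @param network an `igraph` graph.
#' @param coupling_effect log-odds slope on standardized degree.
#' @param base_rate sweep probability of a gene of average degree
#'   (default 0.05).
#' @param seed integer seed (`NULL`: current RNG).
#' @return named logical vector of sweep flags.
#' @export
assign_sweeps_by_centrality <- function(network, coupling_effect,
                                        base_rate = 0.05, seed = NULL) {
  stopifnot(igraph::is_igraph(network), base_rate > 0, base_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  deg <- igraph::degree(network)
  z <- if (sd(deg) > 0) (deg - mean(deg)) / sd(deg) else deg * 0
  p <- plogis(qlogis(base_rate) + coupling_effect * z)
  flags <- rbinom(length(p), 1, p) == 1
  names(flags) <- igraph::V(network)$name
  flags
}
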
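## Topology summaries. All networks here are undirected, so strongly and
## weakly connected components coincide; only the weak definition is
## implemented.

#' Convert a network object to an igraph graph
#'
#' @param x a `pin_integrated`, `pin_subnetwork`, edge-list data.frame or
#'   an igraph graph (returned unchanged).
#' @return an undirected igraph graph, isolated nodes included.
#' @export
pin_graph <- function(x) {
  if (inherits(x, "igraph")) return(x)
  edges <- network_edges(x)
  nodes <- network_nodes(x)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Weakly connected components, largest first
#'
#' @param network any network accepted by [pin_graph()].
#' @return list of character vectors of node names partitioning the nodes,
#'   ordered by decreasing size (ties broken by first node name); the first
#'   element is the largest weakly connected component (LWCC).
#' @export
weakly_connected_components <- function(network) {
  g <- pin_graph(network)
  comp <- igraph::components(g)
  grp <- split(names(comp$membership), comp$membership)
  grp <- lapply(grp, function(x) sort(x))
  ord <- order(-lengths(grp), vapply(grp, `[`, character(1L), 1L))
  unname(grp[ord])
}

dist_stats <- function(g) {
  d <- igraph::distances(g)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (length(v) == 0L) {
    return(list(diameter = NA_integer_, average_path_length = NA_real_))
  }
  list(diameter = as.integer(max(v)), average_path_length = mean(v))
}

#' Diameter and average path length of a connected component
#'
#' Hop distances (BFS). The diameter is the longest shortest-path distance
#' over all node pairs; the average path length is the mean over all
#' unordered pairs.
#'
#' @param component a connected network with at least 2 nodes.
#' @return list with `diameter` (integer) and `average_path_length`.
#' @export
diameter_and_apl <- function(component) {
  g <- pin_graph(component)
  if (igraph::vcount(g) < 2L) stopf("need a component with >= 2 nodes")
  if (igraph::components(g)$no > 1L) {
    stopf("input is disconnected; pass a single connected component")
  }
  dist_stats(g)
}

#' Local clustering coefficient of a node
#'
#' `C_v = 2 e_v / (k_v (k_v - 1))`, where `k_v` is the number of neighbours
#' of `v` and `e_v` the number of edges among them; `C_v = 0` when
#' `k_v < 2`. Self-loops and duplicate edges are excluded from
#' neighbourhoods.
#'
#' @param network any network accepted by [pin_graph()].
#' @param node a node name.
#' @return numeric in [0, 1].
#' @export
clustering_coefficient <- function(network, node) {
  g <- igraph::simplify(pin_graph(network))
  if (!node %in% igraph::V(g)$name) stopf("unknown node: %s", node)
  unname(igraph::transitivity(g, type = "local", vids = node,
                              isolates = "zero"))
}

#' Mean clustering coefficient of a network
#'
#' @param network any network accepted by [pin_graph()].
#' @param include_low_degree if `TRUE` (default) nodes with fewer than two
#'   neighbours contribute `C_v = 0` to the mean; if `FALSE` they are
#'   excluded from the average.
#' @return numeric mean of the local clustering coefficients.
#' @export
network_clustering <- function(network, include_low_degree = TRUE) {
  g <- igraph::simplify(pin_graph(network))
  if (igraph::vcount(g) == 0L) stopf("empty network")
  cc <- igraph::transitivity(g, type = "local",
                             isolates = if (include_low_degree) "zero" else "NaN")
  mean(cc, na.rm = !include_low_degree)
}

#' Average degree of a network
#'
#' Self-loops count twice, the graph-theoretic convention.
#'
#' @param network any network accepted by [pin_graph()].
#' @return numeric mean degree.
#' @export
average_degree <- function(network) {
  g <- pin_graph(network)
  if (igraph::vcount(g) == 0L) stopf("empty network")
  mean(igraph::degree(g, loops = TRUE))
}

#' Index aggregation of a network
#'
#' The fraction of all nodes contained in the largest weakly connected
#' component.
#'
#' @param network any network accepted by [pin_graph()].
#' @return numeric in (0, 1].
#' @export
index_aggregation <- function(network) {
  g <- pin_graph(network)
  if (igraph::vcount(g) == 0L) stopf("empty network")
  max(igraph::components(g)$csize) / igraph::vcount(g)
}

#' Hub proteins
#'
#' @param network any network accepted by [pin_graph()].
#' @param min_degree degree cutoff; nodes with degree strictly greater are
#'   hubs (the conventional cutoff used with this pipeline is 33).
#' @return data.frame with columns `protein`, `degree`, sorted by
#'   decreasing degree (ties by name).
#' @export
hubs <- function(network, min_degree = 33L) {
  g <- pin_graph(network)
  deg <- igraph::degree(g, loops = TRUE)
  sel <- deg[deg > min_degree]
  o <- order(-sel, names(sel))
  data.frame(protein = names(sel)[o], degree = as.integer(sel[o]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Topological feature report
#'
#' Node/edge counts, diameter, average path length, mean clustering
#' coefficient and average degree — computed on the largest weakly
#' connected component by default — plus the index aggregation of the full
#' network.
#'
#' @param network any network accepted by [pin_graph()].
#' @param lwcc_only compute path/clustering/degree statistics on the LWCC
#'   (default) rather than the full network.
#' @return list of class `pin_topology`.
#' @export
topology_report <- function(network, lwcc_only = TRUE) {
  g <- pin_graph(network)
  if (igraph::vcount(g) == 0L) stopf("empty network")
  ia <- index_aggregation(g)
  comps <- weakly_connected_components(g)
  sub <- if (lwcc_only) igraph::induced_subgraph(g, comps[[1L]]) else g
  ds <- if (igraph::vcount(sub) >= 2L) dist_stats(sub)
        else list(diameter = NA_integer_, average_path_length = NA_real_)
  structure(list(n_nodes = igraph::vcount(sub),
                 n_edges = igraph::gsize(sub),
                 diameter = ds$diameter,
                 average_path_length = ds$average_path_length,
                 clustering_coefficient = network_clustering(sub),
                 average_degree = average_degree(sub),
                 index_aggregation = ia,
                 n_components = length(comps),
                 lwcc_only = lwcc_only),
            class = "pin_topology")
}

#' @export
print.pin_topology <- function(x, ...) {
  cat(sprintf(paste0("<pin_topology>%s\n",
                     "  nodes %d  edges %d  components %d\n",
                     "  diameter %s  average path length %s\n",
                     "  clustering coefficient %.3f  average degree %.2f\n",
                     "  index aggregation %.2f%%\n"),
              if (x$lwcc_only) " (largest component)" else "",
              x$n_nodes, x$n_edges, x$n_components,
              format(x$diameter), format(round(x$average_path_length, 3)),
              x$clustering_coefficient, x$average_degree,
              100 * x$index_aggregation))
  invisible(x)
}

#' @export
as.data.frame.pin_topology <- function(x, ...) {
  data.frame(n_nodes = x$n_nodes, n_edges = x$n_edges,
             diameter = x$diameter,
             average_path_length = x$average_path_length,
             clustering_coefficient = x$clustering_coefficient,
             average_degree = x$average_degree,
             index_aggregation = x$index_aggregation,
             stringsAsFactors = FALSE)
}
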
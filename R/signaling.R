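## GO-defined sub-network extraction and evolutionary-origin
## classification.

#' Extract the sub-network of proteins carrying a GO term
#'
#' Seed proteins are the network nodes annotated with `go_id` (pass
#' ancestor-propagated annotations so descendants of the term qualify; see
#' [propagate_annotations()]). The base sub-network keeps the edges among
#' seeds; seeds with no such edge are "isolated". With
#' `expand_neighbors = TRUE` every neighbour of a seed joins the
#' sub-network together with all seed-incident edges.
#'
#' @param network any network accepted by [pin_graph()].
#' @param annotations named list protein -> GO term ids.
#' @param go_id the GO term defining the sub-network, e.g. `"GO:0023052"`
#'   (signaling).
#' @param dag the `go_dag` the annotations refer to; used to validate
#'   `go_id`.
#' @param expand_neighbors also include seed neighbours and seed-neighbour
#'   edges.
#' @return list with `nodes`, `edges` (data.frame), `seeds`,
#'   `isolated_seeds` and `counts` (n_seeds, n_isolated_seeds, n_nodes,
#'   n_edges).
#' @export
extract_go_subnetwork <- function(network, annotations, go_id, dag,
                                  expand_neighbors = FALSE) {
  check_term(dag, go_id)
  nodes <- network_nodes(network)
  edges <- network_edges(network)
  has_term <- vapply(annotations, function(ts) go_id %in% ts, logical(1L))
  seeds <- sort(intersect(nodes, names(annotations)[has_term]))
  seed_a <- edges$protein_a %in% seeds
  seed_b <- edges$protein_b %in% seeds
  base_edges <- edges[seed_a & seed_b, , drop = FALSE]
  isolated <- setdiff(seeds, c(base_edges$protein_a, base_edges$protein_b))
  if (expand_neighbors) {
    out_edges <- edges[seed_a | seed_b, , drop = FALSE]
    out_nodes <- sort(unique(c(seeds, out_edges$protein_a,
                               out_edges$protein_b)))
  } else {
    out_edges <- base_edges
    out_nodes <- seeds
  }
  rownames(out_edges) <- NULL
  list(nodes = out_nodes, edges = out_edges, seeds = seeds,
       isolated_seeds = sort(isolated),
       counts = list(n_seeds = length(seeds),
                     n_isolated_seeds = length(isolated),
                     n_nodes = length(out_nodes),
                     n_edges = nrow(out_edges)))
}

stage_rank <- c(P = 1L, B = 2L, V = 3L)

check_stages <- function(x, what = "stage") {
  bad <- setdiff(unique(x), names(stage_rank))
  if (length(bad)) {
    stopf("invalid %s label(s): %s (must be P, B or V)", what,
          paste(bad, collapse = ", "))
  }
}

#' Evolutionary origin of proteins or interactions
#'
#' The origin of an entity is the earliest evolutionary stage (primitive <
#' bilaterian < vertebrate) among the organisms in which it occurs: P if it
#' exists in any primitive organism, otherwise B if in any bilaterian,
#' otherwise V.
#'
#' @param presence named list mapping each entity to the character vector
#'   of organisms in which it occurs (non-empty).
#' @param stages named character vector organism -> `"P"`, `"B"` or `"V"`.
#' @return named character vector of origin labels.
#' @export
component_origin <- function(presence, stages) {
  check_stages(stages, "organism stage")
  vapply(names(presence), function(id) {
    orgs <- presence[[id]]
    if (length(orgs) == 0L) stopf("entity %s has an empty presence set", id)
    miss <- setdiff(orgs, names(stages))
    if (length(miss)) {
      stopf("entity %s occurs in organism(s) with no stage: %s", id,
            paste(miss, collapse = ", "))
    }
    names(stage_rank)[min(stage_rank[stages[orgs]])]
  }, character(1L))
}

#' Evo-group and complete origin of an interaction
#'
#' The evo-group is the ordered triple of the two protein origins (earliest
#' first) and the interaction origin; the complete origin is the latest
#' stage among the three — the stage in which the last component of the
#' interaction appeared.
#'
#' @param origin_a,origin_b origins of the two proteins (`"P"`, `"B"` or
#'   `"V"`).
#' @param origin_edge origin of the interaction itself.
#' @return list with `evo_group` (e.g. `"PPB"`) and `complete_origin`.
#' @export
interaction_evo_group <- function(origin_a, origin_b, origin_edge) {
  check_stages(c(origin_a, origin_b, origin_edge), "origin")
  proteins <- c(origin_a, origin_b)
  proteins <- proteins[order(stage_rank[proteins])]
  all3 <- c(proteins, origin_edge)
  list(evo_group = paste(all3, collapse = ""),
       complete_origin = names(stage_rank)[max(stage_rank[all3])])
}

#' Origin classification for every interaction in an integrated network
#'
#' Presence of a protein or interaction in an organism is taken from the
#' integration ledgers' source-organism sets.
#'
#' @param network a `pin_integrated` network.
#' @param stages named character vector organism -> `"P"`, `"B"` or `"V"`
#'   covering all source organisms.
#' @return data.frame with columns `protein_a`, `protein_b`, `origin_a`,
#'   `origin_b`, `origin_edge`, `evo_group`, `complete_origin`.
#' @export
edge_origin_table <- function(network, stages) {
  stopifnot(inherits(network, "pin_integrated"))
  check_stages(stages, "organism stage")
  node_origin <- component_origin(lapply(network$nodes, `[[`, "organisms"),
                                  stages)
  keys <- sort(names(network$edges))
  rows <- lapply(keys, function(k) {
    e <- network$edges[[k]]
    oe <- component_origin(setNames(list(e$organisms), k), stages)[[1L]]
    eg <- interaction_evo_group(node_origin[[e$a]], node_origin[[e$b]], oe)
    data.frame(protein_a = e$a, protein_b = e$b,
               origin_a = node_origin[[e$a]], origin_b = node_origin[[e$b]],
               origin_edge = oe, evo_group = eg$evo_group,
               complete_origin = eg$complete_origin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(protein_a = character(0), protein_b = character(0),
                      origin_a = character(0), origin_b = character(0),
                      origin_edge = character(0), evo_group = character(0),
                      complete_origin = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Origin profile of a pathway
#'
#' For the interactions of the network with both endpoints in the pathway
#' member set, the proportion of interactions whose complete origin falls
#' in each evolutionary stage.
#'
#' @param network a `pin_integrated` network.
#' @param members character vector of pathway member proteins.
#' @param stages named character vector organism -> stage (see
#'   [edge_origin_table()]).
#' @return named numeric vector of proportions over the stages observed
#'   (sums to 1); zero-length with a warning if the pathway has no
#'   interaction in the network.
#' @export
pathway_origin_profile <- function(network, members, stages) {
  tab <- edge_origin_table(network, stages)
  keep <- tab$protein_a %in% members & tab$protein_b %in% members
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    warning("pathway has no interaction in the network; empty profile")
    return(setNames(numeric(0), character(0)))
  }
  counts <- table(factor(tab$complete_origin, levels = names(stage_rank)))
  counts <- counts[counts > 0L]
  prop <- as.numeric(counts) / nrow(tab)
  setNames(prop, names(counts))
}
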
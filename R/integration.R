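## Iterative network integration.
##
## The accumulating network is the "target"; at each turn one
## model-organism sub-network (the "query") is merged into it. Every node
## and edge carries a per-turn score ledger:
##   node (point matching):  2 merged with a shared unigene, 1 merged with
##                           disjoint unigenes, 0 not merged this turn
##   edge (edge matching):   3 matched (present in target and query),
##                           2 target-only, 1 newly added from the query,
##                           0 not yet present
## The confidence score of an interaction A-B is
##   S = sum over turns i of (A_i + R_i + B_i)
## where A_i, B_i are the endpoints' node scores and R_i the edge score,
## so with five turns the maximum is 5 * (2 + 3 + 2) = 35.

empty_turn_log <- function() {
  data.frame(turn = integer(0), query_organism = character(0),
             n_nodes = integer(0), n_edges = integer(0),
             stringsAsFactors = FALSE)
}

#' Promote a sub-network to an (initial) integrated network
#'
#' The first sub-network in the integration order becomes the initial
#' target network; its ledgers start at zero and receive their first scores
#' during turn 1 like any target.
#'
#' @param sub a `pin_subnetwork`.
#' @param n_turns total number of integration turns the ledgers must hold.
#' @return object of class `pin_integrated` with fields `n_turns`, `nodes`
#'   (name -> ledger), `edges` (pair key -> ledger) and `turn_log`.
#' @export
as_integrated <- function(sub, n_turns) {
  stopifnot(inherits(sub, "pin_subnetwork"), is_count(n_turns))
  n_turns <- as.integer(n_turns)
  nodes <- setNames(lapply(sub$nodes, function(nm) {
    list(organisms = sub$organism,
         unigenes = sub$protein_to_unigenes[[nm]] %||% character(0),
         members = nm, scores = integer(n_turns))
  }), sub$nodes)
  edges <- list()
  for (i in seq_len(nrow(sub$edges))) {
    pr <- sorted_pair(sub$edges$protein_a[i], sub$edges$protein_b[i])
    edges[[edge_key(pr[1L], pr[2L])]] <-
      list(a = pr[1L], b = pr[2L], organisms = sub$organism,
           scores = integer(n_turns))
  }
  structure(list(n_turns = n_turns, nodes = nodes, edges = edges,
                 turn_log = empty_turn_log()),
            class = "pin_integrated")
}

#' @export
print.pin_integrated <- function(x, ...) {
  cat(sprintf("<pin_integrated> %d proteins, %d interactions, %d/%d turn(s) run\n",
              length(x$nodes), length(x$edges), nrow(x$turn_log), x$n_turns))
  invisible(x)
}

#' Map query proteins to their homologs in the target network
#'
#' For each query protein the first hit (file order) with E-value below the
#' cutoff whose subject is a current target node is selected; the mapping
#' may be many-to-one. When hits against several previously integrated
#' organisms are concatenated, row order encodes the search priority, so
#' earlier-integrated organisms are preferred.
#'
#' @param target a `pin_integrated`, `pin_subnetwork` or character vector
#'   of target node names.
#' @param query a `pin_subnetwork` or character vector of query protein
#'   names.
#' @param hits data.frame of query-vs-target alignment hits (columns
#'   `query`, `subject`, `evalue`, optional `bitscore`).
#' @param evalue_max E-value cutoff (strict `<`).
#' @return named character vector: query protein -> target protein.
#' @export
match_proteins <- function(target, query, hits, evalue_max = 1e-5) {
  target_nodes <- if (inherits(target, "pin_integrated")) names(target$nodes)
                  else if (inherits(target, "pin_subnetwork")) target$nodes
                  else as.character(target)
  query_nodes <- if (inherits(query, "pin_subnetwork")) query$nodes
                 else as.character(query)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(setNames(character(0), character(0)))
  }
  h <- hits[hits$query %in% query_nodes & hits$subject %in% target_nodes, ,
            drop = FALSE]
  if (nrow(h) == 0L) return(setNames(character(0), character(0)))
  h$rank <- seq_len(nrow(h)) - 1L     # concatenated file order
  best_hits(h, evalue_max)
}

#' Merge one query sub-network into the target network (one turn)
#'
#' Applies the merge rules: a query edge whose (mapped) endpoints give an
#' edge already in the target is *matched* (edge score 3 this turn, target
#' names kept); target edges not matched this turn score 2; query edges
#' translating to a new pair are added with score 1, with unmapped query
#' proteins added under their query names. A target node that absorbed at
#' least one homologous query protein scores 2 this turn if the merged
#' proteins share a unigene and 1 otherwise; all other nodes score 0.
#'
#' @param target a `pin_integrated` network.
#' @param query a `pin_subnetwork`.
#' @param mapping named character vector query protein -> target node, as
#'   from [match_proteins()].
#' @param turn_index which turn this is (1-based, at most `n_turns`).
#' @return the updated `pin_integrated` network.
#' @export
merge_turn <- function(target, query, mapping, turn_index) {
  stopifnot(inherits(target, "pin_integrated"),
            inherits(query, "pin_subnetwork"))
  if (!is_count(turn_index) || turn_index > target$n_turns) {
    stopf("turn_index must be an integer in 1..%d", target$n_turns)
  }
  turn_index <- as.integer(turn_index)
  nodes <- target$nodes
  edges <- target$edges
  pre_edge_keys <- names(edges)
  pre_unigenes <- lapply(nodes, `[[`, "unigenes")

  ## Target edges default to "unmatched target edge" (2); matched query
  ## edges upgrade to 3 below.
  for (k in pre_edge_keys) edges[[k]]$scores[turn_index] <- 2L

  mapping <- mapping[names(mapping) %in% query$nodes]
  mapping <- mapping[mapping %in% names(nodes)]

  ## Point matching: each target node absorbing >= 1 homologous query
  ## protein is merged this turn.
  for (t in unique(unname(mapping))) {
    qs <- names(mapping)[mapping == t]
    q_unigenes <- unique(unlist(query$protein_to_unigenes[qs],
                                use.names = FALSE))
    shared <- length(intersect(q_unigenes, pre_unigenes[[t]])) > 0L
    nodes[[t]]$scores[turn_index] <- if (shared) 2L else 1L
    nodes[[t]]$organisms <- union(nodes[[t]]$organisms, query$organism)
    nodes[[t]]$unigenes <- union(nodes[[t]]$unigenes, q_unigenes)
    nodes[[t]]$members <- union(nodes[[t]]$members, qs)
  }

  ## Non-homologous query proteins enter under their own names (score 0).
  for (u in setdiff(query$nodes, names(mapping))) {
    ug <- query$protein_to_unigenes[[u]] %||% character(0)
    if (is.null(nodes[[u]])) {
      nodes[[u]] <- list(organisms = query$organism, unigenes = ug,
                         members = u, scores = integer(target$n_turns))
    } else {
      ## Name collision with an existing node: reuse it, but this is not a
      ## homology merge, so its point-matching score is untouched.
      nodes[[u]]$organisms <- union(nodes[[u]]$organisms, query$organism)
      nodes[[u]]$unigenes <- union(nodes[[u]]$unigenes, ug)
      nodes[[u]]$members <- union(nodes[[u]]$members, u)
    }
  }

  ## Edge matching.
  for (i in seq_len(nrow(query$edges))) {
    u <- query$edges$protein_a[i]
    v <- query$edges$protein_b[i]
    tu <- if (u %in% names(mapping)) unname(mapping[[u]]) else u
    tv <- if (v %in% names(mapping)) unname(mapping[[v]]) else v
    k <- edge_key(tu, tv)
    if (k %in% pre_edge_keys) {
      edges[[k]]$scores[turn_index] <- 3L
      edges[[k]]$organisms <- union(edges[[k]]$organisms, query$organism)
    } else if (!is.null(edges[[k]])) {
      ## Two query edges collapsed onto the same new pair this turn.
      edges[[k]]$organisms <- union(edges[[k]]$organisms, query$organism)
    } else {
      pr <- sorted_pair(tu, tv)
      sc <- integer(target$n_turns)
      sc[turn_index] <- 1L
      edges[[k]] <- list(a = pr[1L], b = pr[2L], organisms = query$organism,
                         scores = sc)
    }
  }

  target$nodes <- nodes
  target$edges <- edges
  target$turn_log <- rbind(target$turn_log, data.frame(
    turn = turn_index, query_organism = query$organism,
    n_nodes = length(nodes), n_edges = length(edges),
    stringsAsFactors = FALSE))
  target
}

#' Integrate an ordered list of sub-networks into one network
#'
#' Sub-networks are merged one by one in the given order (closest genetic
#' relationship first); the first sub-network is the initial target and
#' each of the remaining ones is a query in one turn, so `k` sub-networks
#' yield `k - 1` turns.
#'
#' @param subnetworks list of `pin_subnetwork` objects in integration
#'   order.
#' @param hit_tables named list of cross-organism protein alignment hit
#'   tables; the element `"<query organism>-><target organism>"` holds the
#'   hits of the query organism's proteins against the target organism's
#'   proteins.
#' @param evalue_max E-value cutoff for homology (strict `<`).
#' @return a `pin_integrated` network with fully populated ledgers and a
#'   turn log of non-decreasing node/edge counts.
#' @export
integrate_all <- function(subnetworks, hit_tables, evalue_max = 1e-5) {
  k <- length(subnetworks)
  if (k < 2L) stopf("need at least 2 sub-networks to integrate (got %d)", k)
  for (sn in subnetworks) stopifnot(inherits(sn, "pin_subnetwork"))
  net <- as_integrated(subnetworks[[1L]], k - 1L)
  prev_orgs <- subnetworks[[1L]]$organism
  for (i in 2:k) {
    q <- subnetworks[[i]]
    hits <- gather_hits(hit_tables, q$organism, prev_orgs)
    mapping <- match_proteins(net, q, hits, evalue_max)
    net <- merge_turn(net, q, mapping, i - 1L)
    prev_orgs <- c(prev_orgs, q$organism)
  }
  net
}

## Concatenate the query organism's hit tables against each previously
## integrated organism, in integration order; row order is search priority.
gather_hits <- function(hit_tables, query_org, target_orgs) {
  keys <- paste0(query_org, "->", target_orgs)
  tabs <- hit_tables[intersect(keys, names(hit_tables))]
  tabs <- Filter(function(t) !is.null(t) && nrow(t) > 0L, tabs)
  if (length(tabs) == 0L) return(NULL)
  cols <- c("query", "subject", "evalue", "bitscore")
  tabs <- lapply(tabs, function(t) {
    if (is.null(t$bitscore)) t$bitscore <- 0
    t[, cols, drop = FALSE]
  })
  do.call(rbind, c(tabs, list(make.row.names = FALSE)))
}

#' Confidence score of one interaction
#'
#' Sums, over all integration turns, the edge-matching score and both
#' endpoints' point-matching scores.
#'
#' @param edge an edge ledger (element of `network$edges`).
#' @param node_a,node_b the endpoint node ledgers.
#' @return integer total score.
#' @export
score_interaction <- function(edge, node_a, node_b) {
  if (length(edge$scores) != length(node_a$scores) ||
      length(edge$scores) != length(node_b$scores)) {
    stopf("ledger length mismatch (edge %d, nodes %d/%d)",
          length(edge$scores), length(node_a$scores), length(node_b$scores))
  }
  as.integer(sum(edge$scores + node_a$scores + node_b$scores))
}

edge_total_score <- function(network, key) {
  e <- network$edges[[key]]
  score_interaction(e, network$nodes[[e$a]], network$nodes[[e$b]])
}

#' Per-interaction score table
#'
#' @param network a scored `pin_integrated` network.
#' @return data.frame with one row per interaction: endpoints, source
#'   organisms (comma-joined), the combined per-turn scores
#'   (`score_turn_i` = A_i + R_i + B_i) and the total `score`.
#' @export
interaction_scores <- function(network) {
  stopifnot(inherits(network, "pin_integrated"))
  N <- network$n_turns
  keys <- sort(names(network$edges))
  rows <- lapply(keys, function(k) {
    e <- network$edges[[k]]
    per_turn <- e$scores + network$nodes[[e$a]]$scores +
      network$nodes[[e$b]]$scores
    row <- data.frame(protein_a = e$a, protein_b = e$b,
                      organisms = paste(sort(e$organisms), collapse = ","),
                      stringsAsFactors = FALSE)
    for (i in seq_len(N)) row[[paste0("score_turn_", i)]] <- as.integer(per_turn[i])
    row$score <- as.integer(sum(per_turn))
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(protein_a = character(0), protein_b = character(0),
                      organisms = character(0), stringsAsFactors = FALSE)
    for (i in seq_len(N)) out[[paste0("score_turn_", i)]] <- integer(0)
    out$score <- integer(0)
  }
  out
}

#' Histogram of interaction confidence scores
#'
#' @param network a scored `pin_integrated` network.
#' @param bin_width width of the score bins (default 5, i.e. bins 1-5,
#'   6-10, ...).
#' @return data.frame with columns `bin`, `lower`, `upper`, `count`,
#'   `percent`; percentages sum to 100 when the network has edges.
#' @export
score_distribution <- function(network, bin_width = 5L) {
  stopifnot(inherits(network, "pin_integrated"), is_count(bin_width))
  s <- interaction_scores(network)$score
  max_possible <- 7L * network$n_turns      # per-turn maximum 2 + 3 + 2
  n_bins <- ceiling(max_possible / bin_width)
  lower <- (seq_len(n_bins) - 1L) * bin_width + 1L
  upper <- pmin(seq_len(n_bins) * bin_width, max_possible)
  idx <- ceiling(s / bin_width)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin = paste0(lower, "-", upper), lower = lower, upper = upper,
             count = counts,
             percent = if (length(s)) 100 * counts / length(s) else rep(0, n_bins),
             stringsAsFactors = FALSE)
}

#' Keep only high-confidence interactions
#'
#' @param network a scored `pin_integrated` network.
#' @param min_score minimum total score; edges with `score >= min_score`
#'   are kept and nodes are restricted to the kept edges' endpoints.
#' @return a `pin_integrated` network (ledgers preserved).
#' @export
filter_by_score <- function(network, min_score) {
  stopifnot(inherits(network, "pin_integrated"))
  keep <- names(network$edges)[vapply(names(network$edges), function(k)
    edge_total_score(network, k) >= min_score, logical(1L))]
  network$edges <- network$edges[keep]
  kept_nodes <- unique(unlist(lapply(network$edges,
                                     function(e) c(e$a, e$b)), use.names = FALSE))
  network$nodes <- network$nodes[sort(kept_nodes)]
  network
}

#' Edge list of a network object
#'
#' @param x a `pin_integrated`, `pin_subnetwork` or data.frame.
#' @return data.frame with columns `protein_a`, `protein_b`.
#' @export
network_edges <- function(x) {
  if (inherits(x, "pin_integrated")) {
    keys <- sort(names(x$edges))
    data.frame(protein_a = vapply(x$edges[keys], `[[`, character(1L), "a"),
               protein_b = vapply(x$edges[keys], `[[`, character(1L), "b"),
               row.names = NULL, stringsAsFactors = FALSE)
  } else if (inherits(x, "pin_subnetwork")) {
    x$edges
  } else if (is.data.frame(x)) {
    setNames(x[, 1:2], c("protein_a", "protein_b"))
  } else stopf("cannot extract edges from a %s", class(x)[1L])
}

#' Node names of a network object
#'
#' @param x a `pin_integrated`, `pin_subnetwork` or data.frame edge list.
#' @return character vector of node names.
#' @export
network_nodes <- function(x) {
  if (inherits(x, "pin_integrated")) sort(names(x$nodes))
  else if (inherits(x, "pin_subnetwork")) x$nodes
  else if (is.data.frame(x)) sort(unique(c(x[[1L]], x[[2L]])))
  else stopf("cannot extract nodes from a %s", class(x)[1L])
}
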
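## Independent brute-force oracles. These deliberately avoid igraph and the
## package's own data structures.

## All-pairs shortest hop distances by Floyd-Warshall.
oracle_dists <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]
    b <- edges$protein_b[i]
    if (a != b) d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_diameter_apl <- function(nodes, edges) {
  d <- oracle_dists(nodes, edges)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  list(diameter = max(v), average_path_length = mean(v))
}

## Connected components by union-find.
oracle_components <- function(nodes, edges) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$protein_a[i])
    rb <- find(edges$protein_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1L))
  comps <- split(nodes, roots)
  comps <- lapply(comps, sort)
  ord <- order(-lengths(comps), vapply(comps, `[`, character(1L), 1L))
  unname(comps[ord])
}

## Local clustering coefficients by triple-loop neighbour-pair counting.
oracle_local_cc <- function(nodes, edges) {
  simple <- unique(edges[edges$protein_a != edges$protein_b,
                         c("protein_a", "protein_b")])
  nb <- setNames(lapply(nodes, function(v) {
    sort(unique(c(simple$protein_b[simple$protein_a == v],
                  simple$protein_a[simple$protein_b == v])))
  }), nodes)
  has_edge <- function(x, y) {
    any((simple$protein_a == x & simple$protein_b == y) |
          (simple$protein_a == y & simple$protein_b == x))
  }
  vapply(nodes, function(v) {
    k <- length(nb[[v]])
    if (k < 2L) return(0)
    e <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (has_edge(nb[[v]][i], nb[[v]][j])) e <- e + 1L
      }
    }
    2 * e / (k * (k - 1))
  }, numeric(1L))
}

## Seeded Erdos-Renyi edge list over named nodes.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < p
  list(nodes = nodes,
       edges = data.frame(protein_a = pairs[keep, 1L],
                          protein_b = pairs[keep, 2L],
                          stringsAsFactors = FALSE))
}

## Independent replay of the iterative integration, tracking per-turn
## events with flat named vectors; returns per-edge totals, the final edge
## set and the per-turn query->target renamings.
oracle_integrate <- function(subnets, hit_tables, evalue_max = 1e-5) {
  k <- length(subnets)
  N <- k - 1L
  key <- function(a, b) {
    p <- sort(c(a, b))
    paste(p[1L], p[2L], sep = "|")
  }
  first <- subnets[[1L]]
  node_scores <- list()
  node_unis <- list()
  for (nm in first$nodes) {
    node_scores[[nm]] <- numeric(N)
    node_unis[[nm]] <- first$protein_to_unigenes[[nm]]
  }
  edge_scores <- list()
  edge_ends <- list()
  for (r in seq_len(nrow(first$edges))) {
    kk <- key(first$edges$protein_a[r], first$edges$protein_b[r])
    edge_scores[[kk]] <- numeric(N)
    edge_ends[[kk]] <- sort(c(first$edges$protein_a[r],
                              first$edges$protein_b[r]))
  }
  prev_orgs <- first$organism
  mappings <- list()
  for (i in 2:k) {
    q <- subnets[[i]]
    turn <- i - 1L
    tab_names <- paste0(q$organism, "->", prev_orgs)
    tab <- do.call(rbind, c(unname(hit_tables[intersect(tab_names,
                                                        names(hit_tables))]),
                            list(make.row.names = FALSE)))
    map <- character(0)
    if (!is.null(tab) && nrow(tab)) {
      for (u in q$nodes) {
        rows <- which(tab$query == u & tab$evalue < evalue_max &
                        tab$subject %in% names(node_scores))
        if (length(rows)) map[u] <- tab$subject[rows[1L]]
      }
    }
    mappings[[turn]] <- map
    pre_keys <- names(edge_scores)
    pre_unis <- node_unis
    for (kk in pre_keys) edge_scores[[kk]][turn] <- 2
    for (t in unique(unname(map))) {
      qs <- names(map)[map == t]
      qu <- unique(unlist(q$protein_to_unigenes[qs]))
      node_scores[[t]][turn] <- if (length(intersect(qu, pre_unis[[t]]))) 2 else 1
      node_unis[[t]] <- union(node_unis[[t]], qu)
    }
    for (u in setdiff(q$nodes, names(map))) {
      if (is.null(node_scores[[u]])) {
        node_scores[[u]] <- numeric(N)
        node_unis[[u]] <- q$protein_to_unigenes[[u]]
      } else {
        node_unis[[u]] <- union(node_unis[[u]], q$protein_to_unigenes[[u]])
      }
    }
    for (r in seq_len(nrow(q$edges))) {
      u <- q$edges$protein_a[r]
      v <- q$edges$protein_b[r]
      tu <- if (u %in% names(map)) unname(map[u]) else u
      tv <- if (v %in% names(map)) unname(map[v]) else v
      kk <- key(tu, tv)
      if (kk %in% pre_keys) {
        edge_scores[[kk]][turn] <- 3
      } else if (is.null(edge_scores[[kk]])) {
        edge_scores[[kk]] <- numeric(N)
        edge_scores[[kk]][turn] <- 1
        edge_ends[[kk]] <- sort(c(tu, tv))
      }
    }
    prev_orgs <- c(prev_orgs, q$organism)
  }
  totals <- vapply(names(edge_scores), function(kk) {
    ends <- edge_ends[[kk]]
    sum(edge_scores[[kk]] + node_scores[[ends[1L]]] +
          node_scores[[ends[2L]]])
  }, numeric(1L))
  list(edge_totals = totals, edge_keys = names(edge_scores),
       nodes = sort(names(node_scores)), mappings = mappings)
}

## Independent synchronous neighbor-majority assignment with an adjacency
## matrix.
oracle_assign <- function(edges, annotations, threshold = 0.25) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]
    b <- edges$protein_b[i]
    if (a != b) A[a, b] <- A[b, a] <- TRUE
  }
  ann <- annotations[lengths(annotations) > 0L]
  ann <- ann[names(ann) %in% nodes]
  assigned <- list()
  rounds <- 0L
  repeat {
    new <- list()
    for (u in setdiff(nodes, names(ann))) {
      nbrs <- nodes[A[u, ]]
      nb_ann <- intersect(nbrs, names(ann))
      if (length(nb_ann) == 0L) next
      if (length(nb_ann) == 1L) {
        terms <- sort(unique(ann[[nb_ann]]))
      } else {
        all_terms <- sort(unique(unlist(ann[nb_ann])))
        counts <- vapply(all_terms, function(g)
          sum(vapply(nb_ann, function(v) g %in% ann[[v]], logical(1L))),
          numeric(1L))
        terms <- all_terms[counts / length(nb_ann) > threshold]
      }
      if (length(terms)) new[[u]] <- terms
    }
    if (length(new) == 0L) break
    rounds <- rounds + 1L
    ann <- c(ann, new)
    assigned <- c(assigned, new)
  }
  list(assigned = assigned[sort(names(assigned))], rounds = rounds)
}

## Term ancestor closure by explicit reachability (repeated parent lookup).
oracle_ancestors <- function(dag, term) {
  out <- character(0)
  stack <- dag$terms[[term]]$parents
  while (length(stack)) {
    p <- stack[[1L]]
    stack <- stack[-1L]
    if (p %in% out) next
    out <- c(out, p)
    stack <- c(stack, dag$terms[[p]]$parents)
  }
  sort(out)
}
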
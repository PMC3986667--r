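## Hand-built miniature fixtures used across test files.

make_subnet <- function(organism, pairs, p2u, stage = NA_character_) {
  edges <- data.frame(protein_a = vapply(pairs, `[`, character(1L), 1L),
                      protein_b = vapply(pairs, `[`, character(1L), 2L),
                      stringsAsFactors = FALSE)
  subnetwork(organism, edges, p2u, stage)
}

make_hits <- function(query, subject, evalue, bitscore = 100) {
  data.frame(query = query, subject = subject, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

## The canonical two-network merge scenario: target edges C-D and D-E,
## query edges c-d and d-g with c, d homologous to C, D and g unmatched.
fig7_fixture <- function() {
  target <- make_subnet("T", list(c("C", "D"), c("D", "E")),
                        list(C = "u1", D = "u2", E = "u3"), "B")
  query <- make_subnet("Q", list(c("c", "d"), c("d", "g")),
                       list(c = "u1", d = "u2", g = "u9"), "B")
  hits <- list("Q->T" = make_hits(c("c", "d"), c("C", "D"), c(1e-30, 1e-28)))
  list(target = target, query = query, hits = hits)
}

## Worked example: the merged node of target protein CG6843 and query
## protein CIR-1, both best-hitting the same unigene, built from
## BLAST-style tables through the full best-hit path.
worked_example_fixture <- function() {
  blastx_target <- make_hits(c("Unigene6670_A0A", "Unigene0002_A0A"),
                             c("CG6843", "CG9999"), c(1e-50, 1e-30))
  blastx_query <- make_hits(c("Unigene6670_A0A", "Unigene0002_A0A"),
                            c("CIR-1", "ZK123"), c(1e-45, 1e-25))
  target <- build_subnetwork(
    data.frame(protein_a = "CG6843", protein_b = "CG9999",
               stringsAsFactors = FALSE),
    map_unigenes(best_hits(blastx_target)), "D.melanogaster", "B")
  query <- build_subnetwork(
    data.frame(protein_a = "CIR-1", protein_b = "ZK123",
               stringsAsFactors = FALSE),
    map_unigenes(best_hits(blastx_query)), "C.elegans", "B")
  hits <- list("C.elegans->D.melanogaster" =
                 make_hits(c("CIR-1", "ZK123"), c("CG6843", "CG9999"),
                           c(1e-42, 1e-20)))
  list(target = target, query = query, hits = hits)
}

## Six one-edge sub-networks whose edge is matched in every turn with
## same-unigene node merges: realizes the maximal confidence score.
max_score_fixture <- function() {
  orgs <- paste0("O", 1:6)
  subnets <- lapply(seq_along(orgs), function(i) {
    make_subnet(orgs[i], list(c(paste0("x", i), paste0("y", i))),
                setNames(list("ux", "uy"),
                         c(paste0("x", i), paste0("y", i))))
  })
  hits <- list()
  for (i in 2:6) {
    hits[[paste0(orgs[i], "->", orgs[1L])]] <-
      make_hits(paste0(c("x", "y"), i), c("x1", "y1"), c(1e-40, 1e-40))
  }
  list(subnets = subnets, hits = hits)
}

## Tiny GO DAG: root -> {a, b}; a -> c; {a, b} -> d (two parents).
toy_dag <- function() {
  go_dag(list(
    root = list(id = "GO:0000001", name = "root",
                namespace = "biological_process", parents = character(0)),
    a = list(id = "GO:0000002", name = "a",
             namespace = "biological_process", parents = "GO:0000001"),
    b = list(id = "GO:0000003", name = "b",
             namespace = "biological_process", parents = "GO:0000001"),
    c = list(id = "GO:0000004", name = "c",
             namespace = "biological_process", parents = "GO:0000002"),
    d = list(id = "GO:0000005", name = "d",
             namespace = "biological_process",
             parents = c("GO:0000002", "GO:0000003"))))
}

## igraph graph over a random_graph() result, isolated nodes included.
pin_graph_from <- function(g) {
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

small_universe <- function(seed = 1L, n_families = 40L, ...) {
  generate_universe(universe_config(seed = seed, n_families = n_families,
                                    ...))
}
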
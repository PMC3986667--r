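test_that("annotation propagation closes term sets under is_a ancestors", {
  dag <- toy_dag()
  ann <- list(p1 = "GO:0000004", p2 = c("GO:0000001"))
  out <- propagate_annotations(ann, dag)
  expect_setequal(out$p1, c("GO:0000001", "GO:0000002", "GO:0000004"))
  expect_equal(out$p2, "GO:0000001")
  ## idempotent
  expect_equal(propagate_annotations(out, dag), out)
  ## unknown term rejected
  expect_error(propagate_annotations(list(p = "GO:9999999"), dag),
               "absent from the ontology")
})

test_that("propagated closure equals a reachability oracle on the toy DAG", {
  dag <- toy_dag()
  for (t in names(dag$terms)) {
    expect_setequal(go_ancestors(dag, t), oracle_ancestors(dag, t))
    got <- propagate_annotations(setNames(list(t), "p"), dag)$p
    expect_setequal(got, union(t, oracle_ancestors(dag, t)))
  }
})

test_that("GO sub-network extraction separates seeds, isolated seeds and neighbor expansion", {
  dag <- toy_dag()
  edges <- data.frame(protein_a = paste0("n", 1:4),
                      protein_b = paste0("n", 2:5),
                      stringsAsFactors = FALSE)   # path n1-n2-n3-n4-n5
  ann <- list(n1 = "GO:0000002", n3 = "GO:0000002", n5 = "GO:0000002")
  base <- extract_go_subnetwork(edges, ann, "GO:0000002", dag)
  expect_equal(base$counts$n_nodes, 3L)
  expect_equal(base$counts$n_edges, 0L)
  expect_equal(base$counts$n_isolated_seeds, 3L)
  exp <- extract_go_subnetwork(edges, ann, "GO:0000002", dag,
                               expand_neighbors = TRUE)
  expect_setequal(exp$nodes, paste0("n", 1:5))
  expect_equal(exp$counts$n_edges, 4L)
  ## seed sub-network is contained in the expanded one
  expect_true(all(base$nodes %in% exp$nodes))
  expect_error(extract_go_subnetwork(edges, ann, "GO:1111111", dag),
               "unknown GO term")
})

test_that("extraction counts equal a brute-force filter on an annotated universe", {
  uni <- small_universe(seed = 2L)
  net <- integrate_all(universe_subnetworks(uni), uni$cross_hits)
  ann <- propagate_annotations(
    node_annotations(net, uni$annotations), uni$dag)
  res <- extract_go_subnetwork(net, ann, "GO:0023052", uni$dag,
                               expand_neighbors = TRUE)
  seeds <- sort(names(ann)[vapply(ann, function(ts) "GO:0023052" %in% ts,
                                  logical(1L))])
  seeds <- intersect(seeds, names(net$nodes))
  expect_equal(res$seeds, seeds)
  ed <- network_edges(net)
  touching <- ed$protein_a %in% seeds | ed$protein_b %in% seeds
  both <- ed$protein_a %in% seeds & ed$protein_b %in% seeds
  expect_equal(res$counts$n_edges, sum(touching))
  expect_equal(res$counts$n_isolated_seeds,
               length(setdiff(seeds, unlist(ed[both, 1:2]))))
})

test_that("entity origin is the earliest stage among its organisms", {
  stages <- c(S.cerevisiae = "P", D.melanogaster = "B", C.elegans = "B",
              H.sapiens = "V", R.norvegicus = "V", M.musculus = "V")
  got <- component_origin(list(
    x = c("S.cerevisiae", "H.sapiens"),       # primitive presence -> P
    y = "D.melanogaster",                     # bilaterian only -> B
    z = c("M.musculus", "R.norvegicus")),     # vertebrate only -> V
    stages)
  expect_equal(unname(got), c("P", "B", "V"))
  expect_error(component_origin(list(w = character(0)), stages),
               "empty presence")
  expect_error(component_origin(list(w = "unknown"), stages), "no stage")
})

test_that("complete origin is the latest stage among the triple, over all 27 combinations", {
  stages <- c(P = 1L, B = 2L, V = 3L)
  labels <- names(stages)
  for (a in labels) for (b in labels) for (e in labels) {
    got <- interaction_evo_group(a, b, e)
    expect_equal(got$complete_origin,
                 labels[max(stages[c(a, b, e)])],
                 info = paste(a, b, e))
    ## evo-group lists the protein origins earliest-first, then the edge
    pp <- labels[sort(stages[c(a, b)])]
    expect_equal(got$evo_group, paste0(pp[1L], pp[2L], e))
  }
  ## upgrading any component never downgrades the complete origin
  for (a in labels) for (b in labels) for (e in labels) {
    base <- stages[interaction_evo_group(a, b, e)$complete_origin]
    for (a2 in labels[stages[labels] >= stages[a]]) {
      up <- stages[interaction_evo_group(a2, b, e)$complete_origin]
      expect_gte(up, base)
    }
  }
})

test_that("pathway origin profiles tally complete origins and sum to one", {
  fx <- fig7_fixture()
  net <- integrate_all(list(fx$target, fx$query), fx$hits)
  stages <- c(T = "B", Q = "P")
  tab <- edge_origin_table(net, stages)
  expect_equal(nrow(tab), length(net$edges))
  ## C-D exists in both organisms, so its origin is the earliest stage P
  cd <- tab[tab$protein_a == "C" & tab$protein_b == "D", ]
  expect_equal(cd$origin_edge, "P")
  ## D-E is target-only (stage B)
  de <- tab[tab$protein_a == "D" & tab$protein_b == "E", ]
  expect_equal(de$origin_edge, "B")
  prof <- pathway_origin_profile(net, c("C", "D", "E", "g"), stages)
  expect_equal(sum(prof), 1)
  ## tally oracle
  expect_equal(unname(prof["B"]),
               mean(tab$complete_origin == "B"))
  expect_warning(pathway_origin_profile(net, "absent-protein", stages),
                 "no interaction")
})

test_that("pathway profile recovers the planted pathway's stage composition", {
  uni <- small_universe(seed = 3L)
  net <- integrate_all(universe_subnetworks(uni), uni$cross_hits)
  first_org <- uni$organisms$organism[1L]
  members_src <- uni$proteins[uni$pathway_families, first_org]
  members <- map_members_to_nodes(net, members_src[!is.na(members_src)])
  prof <- suppressWarnings(pathway_origin_profile(net, members, uni$stages))
  if (length(prof)) {
    expect_equal(sum(prof), 1)
    ## oracle: direct tally over the origin table
    tab <- edge_origin_table(net, uni$stages)
    keep <- tab$protein_a %in% members & tab$protein_b %in% members
    want <- table(tab$complete_origin[keep]) / sum(keep)
    expect_equal(unname(prof[names(want)]), unname(as.numeric(want)))
  }
})
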
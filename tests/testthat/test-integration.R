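test_that("the two-network merge scenario scores matched, target-only and new edges correctly", {
  fx <- fig7_fixture()
  net <- integrate_all(list(fx$target, fx$query), fx$hits)
  ## matched edge C-D: present in both networks
  expect_equal(net$edges[[edge_key("C", "D")]]$scores[1L], 3L)
  ## target-only edge D-E
  expect_equal(net$edges[[edge_key("D", "E")]]$scores[1L], 2L)
  ## half-matched query edge d-g becomes D-g, added with score 1
  expect_equal(net$edges[[edge_key("D", "g")]]$scores[1L], 1L)
  ## merged nodes share a unigene with their query counterpart
  expect_equal(net$nodes[["C"]]$scores[1L], 2L)
  expect_equal(net$nodes[["D"]]$scores[1L], 2L)
  ## non-merged nodes score 0
  expect_equal(net$nodes[["E"]]$scores[1L], 0L)
  expect_equal(net$nodes[["g"]]$scores[1L], 0L)
  ## target names are used for merged proteins; c and d disappear
  expect_false(any(c("c", "d") %in% names(net$nodes)))
})

test_that("a fully new query interaction joins under its mapped/unmapped names", {
  ## query edge a-c with c homologous to C and a unmatched: A-C-type pair
  target <- make_subnet("T", list(c("C", "D")), list(C = "u1", D = "u2"))
  query <- make_subnet("Q", list(c("a", "c")), list(a = "u8", c = "u1"))
  net <- integrate_all(list(target, query),
                       list("Q->T" = make_hits("c", "C", 1e-30)))
  expect_true(edge_key("a", "C") %in% names(net$edges))
  expect_equal(net$edges[[edge_key("a", "C")]]$scores[1L], 1L)
})

test_that("the merged node of the worked example scores 2 on the first turn", {
  fx <- worked_example_fixture()
  net <- integrate_all(list(fx$target, fx$query), fx$hits)
  expect_equal(net$nodes[["CG6843"]]$scores[1L], 2L)
  expect_setequal(net$nodes[["CG6843"]]$members, c("CG6843", "CIR-1"))
  expect_equal(net$nodes[["CG6843"]]$unigenes, "Unigene6670_A0A")
})

test_that("merging a network with itself preserves topology and gives uniform scores", {
  uni <- small_universe(seed = 4L)
  sn <- universe_subnetworks(uni)[[1L]]
  identity_hits <- setNames(
    list(make_hits(sn$nodes, sn$nodes, rep(1e-40, length(sn$nodes)))),
    paste0(sn$organism, "->", sn$organism))
  net <- integrate_all(list(sn, sn), identity_hits)
  expect_equal(length(net$nodes), length(sn$nodes))
  expect_equal(length(net$edges), nrow(sn$edges))
  for (e in net$edges) expect_equal(e$scores, 3L)
  for (n in net$nodes) expect_equal(n$scores, 2L)
})

test_that("turn log counts are non-decreasing and ledgers stay within bounds", {
  for (seed in 1:2) {
    uni <- small_universe(seed = seed, n_families = 50L)
    net <- integrate_all(universe_subnetworks(uni), uni$cross_hits)
    tl <- net$turn_log
    expect_equal(nrow(tl), net$n_turns)
    expect_true(all(diff(tl$n_nodes) >= 0))
    expect_true(all(diff(tl$n_edges) >= 0))
    for (n in net$nodes) expect_true(all(n$scores %in% 0:2))
    sc <- interaction_scores(net)
    expect_true(all(sc$score >= 1 & sc$score <= 7 * net$n_turns))
    for (e in net$edges) expect_true(all(e$scores %in% 0:3))
  }
})

test_that("integration conserves every translated input edge and totals match the replay oracle", {
  for (seed in 1:2) {
    uni <- small_universe(seed = seed, n_families = 50L)
    sns <- universe_subnetworks(uni)
    net <- integrate_all(sns, uni$cross_hits)
    orc <- oracle_integrate(sns, uni$cross_hits)
    ## identical final edge sets
    net_keys <- vapply(net$edges, function(e) paste(e$a, e$b, sep = "|"),
                       character(1L))
    expect_setequal(unname(net_keys), orc$edge_keys)
    expect_setequal(names(net$nodes), orc$nodes)
    ## identical per-edge totals (independent event replay)
    sc <- interaction_scores(net)
    got <- setNames(sc$score, paste(sc$protein_a, sc$protein_b, sep = "|"))
    expect_equal(got[sort(names(got))],
                 orc$edge_totals[sort(names(orc$edge_totals))],
                 ignore_attr = TRUE)
    ## conservation: every input edge, translated through its turn's
    ## renaming, appears in the final network
    for (i in seq_along(sns)) {
      map <- if (i == 1L) character(0) else orc$mappings[[i - 1L]]
      edges <- sns[[i]]$edges
      for (r in seq_len(nrow(edges))) {
        tu <- if (edges$protein_a[r] %in% names(map))
          unname(map[edges$protein_a[r]]) else edges$protein_a[r]
        tv <- if (edges$protein_b[r] %in% names(map))
          unname(map[edges$protein_b[r]]) else edges$protein_b[r]
        expect_true(edge_key(tu, tv) %in% names(net$edges),
                    info = sprintf("seed %d subnet %d edge %s-%s", seed, i,
                                   edges$protein_a[r], edges$protein_b[r]))
      }
    }
  }
})

test_that("cross-organism protein matching recovers the planted ortholog pairs", {
  uni <- small_universe(seed = 5L)
  sns <- universe_subnetworks(uni)
  t_org <- uni$organisms$organism[1L]
  q_org <- uni$organisms$organism[2L]
  mapping <- match_proteins(sns[[t_org]], sns[[q_org]],
                            uni$cross_hits[[paste0(q_org, "->", t_org)]])
  ## planted truth: same family, restricted to both sub-networks' nodes
  fam_of <- function(p) sub("_.*$", "", p)
  for (q in names(mapping)) {
    expect_equal(fam_of(mapping[[q]]), fam_of(q))
  }
  planted <- uni$proteins[, t_org][match(fam_of(sns[[q_org]]$nodes),
                                         rownames(uni$proteins))]
  expected <- setNames(planted, sns[[q_org]]$nodes)
  expected <- expected[!is.na(expected) & expected %in% sns[[t_org]]$nodes]
  expect_equal(mapping[sort(names(mapping))],
               expected[sort(names(expected))])
})

test_that("interaction scoring sums node and edge ledgers and enforces consistency", {
  edge <- list(a = "A", b = "B", scores = c(2L, 3L, 3L))
  na <- list(scores = c(0L, 2L, 1L))
  nb <- list(scores = c(0L, 0L, 2L))
  expect_equal(score_interaction(edge, na, nb), 2 + 3 + 3 + 2 + 1 + 2)
  expect_error(score_interaction(edge, list(scores = 1L), nb),
               "ledger length mismatch")
})

test_that("score distribution bins by width 5 and percentages sum to 100", {
  fx <- max_score_fixture()
  net <- integrate_all(fx$subnets, fx$hits)
  dist <- score_distribution(net)
  expect_equal(sum(dist$percent), 100, tolerance = 1e-9)
  expect_equal(dist$count[dist$bin == "31-35"], 1L)
  expect_equal(sum(dist$count), length(net$edges))
  ## distribution equals a direct tally on a larger fixture
  uni <- small_universe(seed = 1L)
  net2 <- integrate_all(universe_subnetworks(uni), uni$cross_hits)
  s <- interaction_scores(net2)$score
  dist2 <- score_distribution(net2)
  for (i in seq_len(nrow(dist2))) {
    expect_equal(dist2$count[i],
                 sum(s >= dist2$lower[i] & s <= dist2$upper[i]))
  }
  expect_equal(sum(dist2$percent), 100, tolerance = 1e-9)
})

test_that("score filtering keeps high-confidence edges and their endpoints only", {
  uni <- small_universe(seed = 1L)
  net <- integrate_all(universe_subnetworks(uni), uni$cross_hits)
  s <- interaction_scores(net)$score
  ## min_score = 1 is the identity
  expect_equal(length(filter_by_score(net, 1L)$edges), length(net$edges))
  ## above the theoretical maximum: empty
  expect_equal(length(filter_by_score(net, 7L * net$n_turns + 1L)$edges), 0L)
  cutoff <- as.integer(stats::median(s))
  high <- filter_by_score(net, cutoff)
  expect_equal(length(high$edges), sum(s >= cutoff))
  expect_setequal(names(high$nodes),
                  unique(unlist(lapply(high$edges, function(e) c(e$a, e$b)))))
  expect_true(all(interaction_scores(high)$score >= cutoff))
})

test_that("integration validates its inputs", {
  fx <- fig7_fixture()
  expect_error(integrate_all(list(fx$target), fx$hits), "at least 2")
  net <- as_integrated(fx$target, 1L)
  expect_error(merge_turn(net, fx$query, character(0), 2L), "turn_index")
  expect_error(merge_turn(net, fx$query, character(0), 0L), "turn_index")
})

test_that("consistent identifier permutation yields an isomorphic scored network", {
  fx <- fig7_fixture()
  net1 <- integrate_all(list(fx$target, fx$query), fx$hits)
  ## permute every identifier with a fixed prefix map
  rn <- function(x) paste0("z", x, "9")
  target2 <- make_subnet("T", list(c(rn("C"), rn("D")), c(rn("D"), rn("E"))),
                         setNames(list("u1", "u2", "u3"),
                                  rn(c("C", "D", "E"))), "B")
  query2 <- make_subnet("Q", list(c(rn("c"), rn("d")), c(rn("d"), rn("g"))),
                        setNames(list("u1", "u2", "u9"),
                                 rn(c("c", "d", "g"))), "B")
  hits2 <- list("Q->T" = make_hits(rn(c("c", "d")), rn(c("C", "D")),
                                   c(1e-30, 1e-28)))
  net2 <- integrate_all(list(target2, query2), hits2)
  s1 <- interaction_scores(net1)
  s2 <- interaction_scores(net2)
  expect_equal(sort(s2$score), sort(s1$score))
  expect_equal(length(net2$nodes), length(net1$nodes))
  for (nm in names(net1$nodes)) {
    expect_equal(net2$nodes[[rn(nm)]]$scores, net1$nodes[[nm]]$scores)
  }
})
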
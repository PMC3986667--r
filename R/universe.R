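#' The six model organisms with stages and retention defaults
#'
#' Integration order (closest genetic relationship to the target organism
#' first), evolutionary stage (P primitive, B bilaterian, V vertebrate) and
#' the default per-organism probability that an ortholog family retains a
#' protein in the synthetic universe.
#'
#' @return data.frame with columns `organism`, `stage`, `retention_prob`.
#' @export
default_organisms <- function() {
  data.frame(
    organism = c("D.melanogaster", "C.elegans", "H.sapiens",
                 "R.norvegicus", "M.musculus", "S.cerevisiae"),
    stage = c("B", "B", "V", "V", "V", "P"),
    retention_prob = c(0.9, 0.85, 0.9, 0.75, 0.8, 0.8),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic multi-organism universe
#'
#' Defines the study conditions the generator emulates: ortholog families
#' shared across organisms with stage-dependent retention, family-level
#' interactions partially conserved per organism, unigene-to-protein
#' homology with E-values cleanly separated around the 1e-5 cutoff, a small
#' rooted GO DAG including a "signaling" term, partial annotation coverage,
#' and a planted connected pathway with planted function labels as ground
#' truth.
#'
#' @param seed RNG seed; the whole universe is a deterministic function of
#'   the configuration.
#' @param n_families number of ortholog families.
#' @param organisms data.frame with columns `organism`, `stage`,
#'   `retention_prob`, in integration order.
#' @param edge_density probability that a family pair interacts.
#' @param interaction_conservation probability that a family-level
#'   interaction is realized in an organism possessing both families.
#' @param unigene_coverage fraction of families matched by at least one
#'   unigene of the target organism.
#' @param multi_unigene_prob probability a covered family maps to two
#'   unigenes.
#' @param annotation_coverage probability a protein carries its family's
#'   GO labels.
#' @param n_go_terms number of terms in the toy GO DAG (>= 3).
#' @param go_max_depth maximum depth of the toy DAG.
#' @param n_pathway_families number of families in the planted pathway.
#' @param n_decoy_hits decoy (above-cutoff) hits added per query in every
#'   homology table.
#' @return object of class `pin_universe_config`.
#' @export
universe_config <- function(seed = 1L, n_families = 50L,
                            organisms = default_organisms(),
                            edge_density = 0.08,
                            interaction_conservation = 0.7,
                            unigene_coverage = 0.9,
                            multi_unigene_prob = 0.15,
                            annotation_coverage = 0.7,
                            n_go_terms = 30L, go_max_depth = 6L,
                            n_pathway_families = 8L, n_decoy_hits = 1L) {
  if (!is.data.frame(organisms) || nrow(organisms) == 0L ||
      !all(c("organism", "stage", "retention_prob") %in% names(organisms))) {
    stopf("organisms must be a non-empty data.frame with columns organism, stage, retention_prob")
  }
  check_stages(organisms$stage, "organism stage")
  for (p in c(organisms$retention_prob, edge_density,
              interaction_conservation, unigene_coverage,
              multi_unigene_prob, annotation_coverage)) {
    if (!is_prob(p)) stopf("all probabilities must lie in [0, 1] (got %s)", p)
  }
  for (n in list(n_families, n_go_terms, go_max_depth, n_pathway_families)) {
    if (!is_count(n)) stopf("counts must be integers >= 1 (got %s)", n)
  }
  if (n_go_terms < 3L) stopf("n_go_terms must be at least 3")
  if (!is.numeric(n_decoy_hits) || n_decoy_hits < 0) {
    stopf("n_decoy_hits must be a non-negative integer")
  }
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 organisms = organisms, edge_density = edge_density,
                 interaction_conservation = interaction_conservation,
                 unigene_coverage = unigene_coverage,
                 multi_unigene_prob = multi_unigene_prob,
                 annotation_coverage = annotation_coverage,
                 n_go_terms = as.integer(n_go_terms),
                 go_max_depth = as.integer(go_max_depth),
                 n_pathway_families = as.integer(n_pathway_families),
                 n_decoy_hits = as.integer(n_decoy_hits)),
            class = "pin_universe_config")
}

## E-value sampling: true homologs fall log-uniformly well below the 1e-5
## cutoff, decoys log-uniformly above it, so best-hit selection separates
## them perfectly by construction.
r_true_evalue <- function(n) 10^runif(n, -50, -6)
r_decoy_evalue <- function(n) 10^runif(n, -4, 0)

blast_row <- function(query, subject, evalue, true_hit) {
  len <- sample(100:500, 1L)
  data.frame(query = query, subject = subject,
             pident = round(if (true_hit) runif(1, 60, 100) else runif(1, 20, 40), 1),
             length = len, mismatch = sample(0:20, 1L),
             gapopen = sample(0:3, 1L), qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = evalue,
             bitscore = round(if (true_hit) runif(1, 80, 300) else runif(1, 20, 40), 1),
             stringsAsFactors = FALSE)
}

finish_blast_table <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(query = character(0), subject = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  df <- df[order(df$query, df$evalue, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df$rank <- as.integer(ave(seq_len(nrow(df)), df$query, FUN = seq_along) - 1L)
  df
}

#' Generate a synthetic multi-organism universe
#'
#' Deterministic given the configuration seed. Families are sampled into
#' organisms by retention probability (planted-pathway families are always
#' present in the first organism, so the planted pathway is connected there
#' when `interaction_conservation = 1`); family-level interactions are
#' realized per organism; unigene-vs-proteome and cross-organism homology
#' hit tables carry true hits below the E-value cutoff and decoys above it;
#' a rooted GO DAG containing a "signaling" term (GO:0023052) is grown by
#' attaching each new term to 1-2 existing parents; planted per-family
#' function labels drive partial protein annotation.
#'
#' @param config a [universe_config()].
#' @return object of class `pin_universe`; see Details for fields.
#' @details Fields: `config`, `organisms`, `stages` (named vector),
#'   `families`, `presence` (family x organism logical matrix), `proteins`
#'   (family x organism id matrix, NA when absent), `family_edges`
#'   (data.frame with `pathway` flag), `interactions` (per-organism edge
#'   data.frames), `unigene_map` (data.frame unigene/family),
#'   `unigene_hits` (per-organism BLAST-like tables), `cross_hits` (tables
#'   keyed `"query_org->target_org"` for every ordered organism pair),
#'   `dag`, `annotations`, `planted_labels` (family -> terms),
#'   `pathway_families`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "pin_universe_config"))
  set.seed(config$seed)
  orgs <- config$organisms
  n_org <- nrow(orgs)
  nf <- config$n_families
  fam <- sprintf("F%03d", seq_len(nf))
  codes <- org_codes(orgs$organism)

  presence <- matrix(runif(nf * n_org) < rep(orgs$retention_prob, each = nf),
                     nrow = nf, dimnames = list(fam, orgs$organism))
  pathway_families <- sort(sample(fam, min(config$n_pathway_families, nf)))
  presence[pathway_families, 1L] <- TRUE

  proteins <- outer(fam, codes, paste, sep = "_")
  dimnames(proteins) <- list(fam, orgs$organism)
  proteins[!presence] <- NA_character_

  ## Family-level interactions + a chain through the planted pathway.
  pairs <- if (nf >= 2L) t(combn(fam, 2L)) else matrix(character(0), ncol = 2L)
  keep <- runif(nrow(pairs)) < config$edge_density
  fe <- data.frame(family_a = pairs[keep, 1L], family_b = pairs[keep, 2L],
                   pathway = rep(FALSE, sum(keep)), stringsAsFactors = FALSE)
  if (length(pathway_families) >= 2L) {
    chain <- data.frame(family_a = pathway_families[-length(pathway_families)],
                        family_b = pathway_families[-1L], pathway = TRUE,
                        stringsAsFactors = FALSE)
    fe <- rbind(fe, chain)
  }
  if (nrow(fe)) {
    cp <- canonicalize_pairs(fe$family_a, fe$family_b)
    fe$family_a <- cp$protein_a
    fe$family_b <- cp$protein_b
    key <- paste(fe$family_a, fe$family_b, sep = "\t")
    fe <- data.frame(family_a = fe$family_a[!duplicated(key)],
                     family_b = fe$family_b[!duplicated(key)],
                     pathway = as.logical(tapply(fe$pathway, key, any)[key[!duplicated(key)]]),
                     stringsAsFactors = FALSE)
    fe <- fe[order(fe$family_a, fe$family_b, method = "radix"), , drop = FALSE]
    rownames(fe) <- NULL
  }

  ## Realize interactions per organism.
  interactions <- setNames(vector("list", n_org), orgs$organism)
  for (j in seq_len(n_org)) {
    rows <- list()
    for (i in seq_len(nrow(fe))) {
      fa <- fe$family_a[i]
      fb <- fe$family_b[i]
      if (presence[fa, j] && presence[fb, j] &&
          runif(1) < config$interaction_conservation) {
        rows[[length(rows) + 1L]] <- canonicalize_pairs(proteins[fa, j],
                                                        proteins[fb, j])
      }
    }
    interactions[[j]] <- if (length(rows)) {
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    } else {
      data.frame(protein_a = character(0), protein_b = character(0),
                 stringsAsFactors = FALSE)
    }
  }

  ## Unigenes of the target organism: 1-2 per covered family.
  covered <- fam[runif(nf) < config$unigene_coverage]
  uni_rows <- list()
  counter <- 0L
  for (f in covered) {
    n_uni <- 1L + as.integer(runif(1) < config$multi_unigene_prob)
    for (u in seq_len(n_uni)) {
      counter <- counter + 1L
      uni_rows[[counter]] <- data.frame(
        unigene = sprintf("Unigene%04d_A0A", counter), family = f,
        stringsAsFactors = FALSE)
    }
  }
  unigene_map <- if (length(uni_rows)) {
    do.call(rbind, c(uni_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(unigene = character(0), family = character(0),
               stringsAsFactors = FALSE)
  }

  ## Unigene-vs-proteome hit tables (one per organism).
  unigene_hits <- setNames(vector("list", n_org), orgs$organism)
  for (j in seq_len(n_org)) {
    rows <- list()
    org_proteins <- proteins[presence[, j], j]
    for (i in seq_len(nrow(unigene_map))) {
      u <- unigene_map$unigene[i]
      f <- unigene_map$family[i]
      if (presence[f, j]) {
        rows[[length(rows) + 1L]] <-
          blast_row(u, proteins[f, j], r_true_evalue(1L), TRUE)
      }
      decoy_pool <- setdiff(org_proteins, proteins[f, j])
      n_dec <- min(config$n_decoy_hits, length(decoy_pool))
      if (n_dec > 0L) {
        for (s in sample(decoy_pool, n_dec)) {
          rows[[length(rows) + 1L]] <- blast_row(u, s, r_decoy_evalue(1L), FALSE)
        }
      }
    }
    unigene_hits[[j]] <- finish_blast_table(rows)
  }

  ## Cross-organism protein-vs-protein hit tables, every ordered pair.
  cross_hits <- list()
  for (jq in seq_len(n_org)) {
    for (jt in seq_len(n_org)) {
      if (jq == jt) next
      rows <- list()
      target_proteins <- proteins[presence[, jt], jt]
      shared <- fam[presence[, jq] & presence[, jt]]
      for (f in shared) {
        rows[[length(rows) + 1L]] <-
          blast_row(proteins[f, jq], proteins[f, jt], r_true_evalue(1L), TRUE)
        decoy_pool <- setdiff(target_proteins, proteins[f, jt])
        n_dec <- min(config$n_decoy_hits, length(decoy_pool))
        if (n_dec > 0L) {
          for (s in sample(decoy_pool, n_dec)) {
            rows[[length(rows) + 1L]] <-
              blast_row(proteins[f, jq], s, r_decoy_evalue(1L), FALSE)
          }
        }
      }
      cross_hits[[paste0(orgs$organism[jq], "->", orgs$organism[jt])]] <-
        finish_blast_table(rows)
    }
  }

  ## Toy GO DAG: root, a signaling term, then random attachment.
  root_id <- "GO:0000001"
  sig_id <- "GO:0023052"
  terms <- list()
  terms[[root_id]] <- list(id = root_id, name = "biological_process",
                           namespace = "biological_process",
                           parents = character(0))
  terms[[sig_id]] <- list(id = sig_id, name = "signaling",
                          namespace = "biological_process",
                          parents = root_id)
  depth <- c(1L, 2L)
  names(depth) <- c(root_id, sig_id)
  for (i in seq_len(config$n_go_terms - 2L)) {
    id <- sprintf("GO:%07d", 100L + i)
    if (i <= 2L) {
      parents <- sig_id          # guarantee signaling descendants exist
    } else {
      eligible <- names(depth)[depth < config$go_max_depth]
      n_par <- min(sample(1:2, 1L), length(eligible))
      parents <- sample(eligible, n_par)
    }
    terms[[id]] <- list(id = id, name = paste0("process_", i),
                        namespace = "biological_process", parents = parents)
    depth[id] <- min(depth[parents]) + 1L
  }
  dag <- go_dag(terms)

  ## Planted function labels per family; pathway families are signaling.
  sig_desc <- names(dag$terms)[vapply(names(dag$terms), function(t)
    sig_id %in% c(t, go_ancestors(dag, t)), logical(1L))]
  sig_desc <- setdiff(sig_desc, sig_id)
  non_root <- setdiff(names(dag$terms), root_id)
  non_sig <- setdiff(non_root, c(sig_id, sig_desc))
  planted_labels <- setNames(vector("list", nf), fam)
  for (f in fam) {
    n_terms <- sample(1:2, 1L)
    if (f %in% pathway_families && length(sig_desc)) {
      ## Pathway families carry a signaling-descendant label so the planted
      ## pathway is recoverable through GO-based extraction.
      labs <- c(sample(sig_desc, 1L),
                if (n_terms > 1L) sample(non_root, n_terms - 1L))
    } else {
      pool <- if (length(non_sig)) non_sig else non_root
      labs <- sample(pool, min(n_terms, length(pool)))
    }
    planted_labels[[f]] <- sort(unique(labs))
  }

  ## Partial annotation, gated per family: either all of a family's
  ## proteins carry its labels or none do, so roughly annotation_coverage
  ## of proteins (and of merged network nodes) are annotated.
  annotated_families <- fam[runif(nf) < config$annotation_coverage]
  annotations <- list()
  for (j in seq_len(n_org)) {
    for (f in intersect(annotated_families, fam[presence[, j]])) {
      annotations[[proteins[f, j]]] <- planted_labels[[f]]
    }
  }

  structure(list(config = config, organisms = orgs,
                 stages = setNames(orgs$stage, orgs$organism),
                 families = fam, presence = presence, proteins = proteins,
                 family_edges = fe, interactions = interactions,
                 unigene_map = unigene_map, unigene_hits = unigene_hits,
                 cross_hits = cross_hits, dag = dag,
                 annotations = annotations,
                 planted_labels = planted_labels,
                 pathway_families = pathway_families),
            class = "pin_universe")
}

#' @export
print.pin_universe <- function(x, ...) {
  cat(sprintf("<pin_universe> seed %d: %d families, %d organisms, %d GO terms, %d annotated proteins\n",
              x$config$seed, length(x$families), nrow(x$organisms),
              length(x$dag$terms), length(x$annotations)))
  invisible(x)
}

#' Planted unigene-to-protein ortholog map of one organism
#'
#' The ground truth that best-hit selection on the universe's unigene hit
#' tables should recover exactly.
#'
#' @param universe a `pin_universe`.
#' @param organism organism name.
#' @return named character vector unigene -> protein.
#' @export
planted_unigene_map <- function(universe, organism) {
  um <- universe$unigene_map
  keep <- universe$presence[um$family, organism]
  setNames(universe$proteins[um$family[keep], organism], um$unigene[keep])
}

#' Build the per-organism sub-networks of a universe
#'
#' Convenience wrapper running best-hit selection, unigene map inversion
#' and sub-network construction for every organism.
#'
#' @param universe a `pin_universe`.
#' @param evalue_max E-value cutoff.
#' @return named list of `pin_subnetwork` objects in integration order.
#' @export
universe_subnetworks <- function(universe, evalue_max = 1e-5) {
  stopifnot(inherits(universe, "pin_universe"))
  out <- list()
  for (j in seq_len(nrow(universe$organisms))) {
    org <- universe$organisms$organism[j]
    bh <- best_hits(universe$unigene_hits[[org]], evalue_max)
    p2u <- map_unigenes(bh)
    out[[org]] <- build_subnetwork(universe$interactions[[org]], p2u, org,
                                   universe$organisms$stage[j])
  }
  out
}
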
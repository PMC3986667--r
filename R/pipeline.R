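#' Pipeline configuration
#'
#' Bundles every tunable of the full analysis arc with its conventional
#' default: homology E-value cutoff 1e-5 (strict), score bin width 5,
#' high-confidence score cutoff 30, hub degree cutoff 33, signaling GO term
#' GO:0023052, neighbor-majority threshold 0.25.
#'
#' @param out_dir output directory for all artifacts.
#' @param universe a [universe_config()] describing the synthetic inputs;
#'   ignored when `input_dir` points at an existing fixture directory.
#' @param input_dir optional directory in the [write_fixture()] layout to
#'   run on instead of generating a universe.
#' @param evalue_max homology E-value cutoff.
#' @param bin_width score histogram bin width.
#' @param high_score_cutoff minimum total score of the high-confidence
#'   network.
#' @param hub_degree_cutoff hubs have degree strictly greater than this.
#' @param signaling_go_id GO term defining the signaling sub-network.
#' @param assignment_threshold neighbor-majority support threshold.
#' @return object of class `pin_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, universe = universe_config(),
                            input_dir = NULL, evalue_max = 1e-5,
                            bin_width = 5L, high_score_cutoff = 30L,
                            hub_degree_cutoff = 33L,
                            signaling_go_id = "GO:0023052",
                            assignment_threshold = 0.25) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  if (is.null(input_dir)) stopifnot(inherits(universe, "pin_universe_config"))
  structure(list(out_dir = out_dir, universe = universe,
                 input_dir = input_dir, evalue_max = evalue_max,
                 bin_width = as.integer(bin_width),
                 high_score_cutoff = as.integer(high_score_cutoff),
                 hub_degree_cutoff = as.integer(hub_degree_cutoff),
                 signaling_go_id = signaling_go_id,
                 assignment_threshold = assignment_threshold),
            class = "pin_pipeline_config")
}

## Annotations are recorded per source protein; an integrated node carries
## the union over every protein merged into it.
node_annotations <- function(network, annotations) {
  out <- lapply(network$nodes, function(n) {
    sort(unique(unlist(annotations[n$members], use.names = FALSE)))
  })
  out[lengths(out) > 0L]
}

## Map pathway member proteins (source-organism ids) to integrated node
## names through the merge ledgers.
map_members_to_nodes <- function(network, members) {
  hit <- vapply(network$nodes, function(n)
    length(intersect(n$members, members)) > 0L, logical(1L))
  sort(names(network$nodes)[hit])
}

#' Run the full analysis pipeline
#'
#' Fixture generation (or reading), sub-network construction, iterative
#' integration with scoring, topology, signaling sub-network extraction,
#' evolutionary-origin classification, pathway origin profiles and
#' neighbor-majority function assignment. Every stage writes a TSV
#' artifact; a YAML manifest with md5 checksums and a run log close the
#' run. Identical configuration implies identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param force overwrite a non-empty output directory.
#' @return the manifest (data.frame `path`, `md5`), invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pin_pipeline_config"))
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out, all.files = FALSE)) > 0L && !force) {
    stopf("output directory %s is not empty; use force = TRUE to overwrite",
          out)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  ## Stage 1: inputs.
  if (is.null(config$input_dir)) {
    note("[fixture] generating synthetic universe (seed %d, %d families)",
         config$universe$seed, config$universe$n_families)
    uni <- generate_universe(config$universe)
    write_fixture(uni, file.path(out, "fixture"))
    input_dir <- file.path(out, "fixture")
  } else {
    input_dir <- config$input_dir
    note("[fixture] using inputs from %s", input_dir)
  }
  inputs <- read_fixture(input_dir)
  orgs <- inputs$organisms
  if (nrow(orgs) < 2L) {
    stopf("pipeline needs at least 2 organisms in the integration order (got %d)",
          nrow(orgs))
  }

  ## Stage 2: per-organism sub-networks.
  subnets <- list()
  for (j in seq_len(nrow(orgs))) {
    org <- orgs$organism[j]
    bh <- best_hits(inputs$unigene_hits[[org]], config$evalue_max)
    p2u <- map_unigenes(bh)
    subnets[[org]] <- build_subnetwork(inputs$interactions[[org]], p2u, org,
                                       orgs$stage[j])
    note("[subnet] %s: %d proteins, %d interactions", org,
         length(subnets[[org]]$nodes), nrow(subnets[[org]]$edges))
  }
  sn_summary <- subnetwork_summary(subnets)
  write_tsv(sn_summary, file.path(out, "subnetworks_summary.tsv"))

  ## Stage 3: integration and scoring.
  net <- integrate_all(subnets, inputs$cross_hits, config$evalue_max)
  note("[integrate] %d turns -> %d proteins, %d interactions",
       net$n_turns, length(net$nodes), length(net$edges))
  write_network(net, file.path(out, "network.tsv"))
  write_tsv(net$turn_log, file.path(out, "turn_log.tsv"))
  write_tsv(interaction_scores(net), file.path(out, "scores.tsv"))
  write_tsv(score_distribution(net, config$bin_width),
            file.path(out, "score_distribution.tsv"))
  high <- filter_by_score(net, config$high_score_cutoff)
  write_tsv(interaction_scores(high), file.path(out, "high_score_edges.tsv"))
  write_tsv(hubs(net, config$hub_degree_cutoff), file.path(out, "hubs.tsv"))
  note("[score] %d interactions with score >= %d; %d hub(s) with degree > %d",
       length(high$edges), config$high_score_cutoff,
       nrow(hubs(net, config$hub_degree_cutoff)), config$hub_degree_cutoff)

  ## Stage 4: topology (per sub-network LWCC and integrated LWCC).
  topo_rows <- lapply(c(subnets, list(integrated = net)), function(x) {
    as.data.frame(topology_report(x))
  })
  topo <- do.call(rbind, c(topo_rows, list(make.row.names = FALSE)))
  topo <- cbind(data.frame(network = c(orgs$organism, "integrated"),
                           stringsAsFactors = FALSE), topo)
  write_tsv(topo, file.path(out, "topology.tsv"))

  ## Stage 5: signaling sub-network and evolution.
  ann_nodes <- node_annotations(net, inputs$annotations)
  ann_prop <- propagate_annotations(ann_nodes, inputs$dag)
  sig <- extract_go_subnetwork(net, ann_prop, config$signaling_go_id,
                               inputs$dag, expand_neighbors = TRUE)
  note("[signaling] %d seed proteins (%d isolated), expanded sub-network: %d proteins, %d interactions",
       sig$counts$n_seeds, sig$counts$n_isolated_seeds,
       sig$counts$n_nodes, sig$counts$n_edges)
  sig_edges <- sig$edges
  if (nrow(sig_edges)) {
    sig_edges$seed_a <- sig_edges$protein_a %in% sig$seeds
    sig_edges$seed_b <- sig_edges$protein_b %in% sig$seeds
  }
  write_tsv(sig_edges, file.path(out, "signaling_edges.tsv"))
  write_tsv(data.frame(protein = sig$seeds,
                       isolated = sig$seeds %in% sig$isolated_seeds,
                       stringsAsFactors = FALSE),
            file.path(out, "signaling_seeds.tsv"))

  origins <- edge_origin_table(net, inputs$stages)
  write_tsv(origins, file.path(out, "edge_origins.tsv"))
  profile_rows <- list()
  for (pw in names(inputs$pathways)) {
    members <- map_members_to_nodes(net, inputs$pathways[[pw]])
    prof <- suppressWarnings(pathway_origin_profile(net, members,
                                                    inputs$stages))
    if (length(prof)) {
      profile_rows[[pw]] <- data.frame(pathway = pw, origin = names(prof),
                                       proportion = as.numeric(prof),
                                       stringsAsFactors = FALSE)
    }
  }
  profiles <- if (length(profile_rows)) {
    do.call(rbind, c(profile_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(pathway = character(0), origin = character(0),
               proportion = numeric(0), stringsAsFactors = FALSE)
  }
  write_tsv(profiles, file.path(out, "pathway_origin_profiles.tsv"))

  ## Stage 6: function assignment of unclassified proteins.
  res <- assign_functions(net, ann_nodes, config$assignment_threshold)
  n_unclassified <- length(net$nodes) - length(ann_nodes)
  coverage <- if (n_unclassified > 0) length(res$assigned) / n_unclassified
              else NA_real_
  note("[assign] %d of %d unclassified proteins assigned (%.0f%%) in %d round(s)",
       length(res$assigned), n_unclassified,
       if (is.na(coverage)) 0 else 100 * coverage, res$rounds)
  assign_rows <- lapply(names(res$assigned), function(p) {
    data.frame(protein = p,
               unigenes = paste(net$nodes[[p]]$unigenes, collapse = ","),
               go_id = res$assigned[[p]],
               go_depth = go_depths(inputs$dag)[res$assigned[[p]]],
               stringsAsFactors = FALSE)
  })
  assigned_df <- if (length(assign_rows)) {
    do.call(rbind, c(assign_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(protein = character(0), unigenes = character(0),
               go_id = character(0), go_depth = integer(0),
               stringsAsFactors = FALSE)
  }
  write_tsv(assigned_df, file.path(out, "assigned_functions.tsv"))
  write_tsv(depth_distribution(res, inputs$dag),
            file.path(out, "assignment_depths.tsv"))

  writeLines(log_lines, file.path(out, "run_log.txt"))
  artifacts <- c("subnetworks_summary.tsv", "network.tsv", "turn_log.tsv",
                 "scores.tsv", "score_distribution.tsv",
                 "high_score_edges.tsv", "hubs.tsv", "topology.tsv",
                 "signaling_edges.tsv", "signaling_seeds.tsv",
                 "edge_origins.tsv", "pathway_origin_profiles.tsv",
                 "assigned_functions.tsv", "assignment_depths.tsv",
                 "run_log.txt")
  manifest <- data.frame(path = artifacts,
                         md5 = unname(md5sum(file.path(out, artifacts))),
                         stringsAsFactors = FALSE)
  yaml::write_yaml(list(files = lapply(seq_len(nrow(manifest)), function(i)
    list(path = manifest$path[i], md5 = manifest$md5[i]))),
    file.path(out, "manifest.yaml"))
  invisible(manifest)
}

#' Human-readable summary of a pipeline run
#'
#' @param out_dir the output directory of a completed [run_pipeline()].
#' @return the report lines, invisibly; printed to the console.
#' @export
pipeline_report <- function(out_dir) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  read_art <- function(name) {
    path <- file.path(out_dir, name)
    if (!file.exists(path)) {
      warning(sprintf("missing artifact: %s (partial report)", name))
      return(NULL)
    }
    read.delim(path, stringsAsFactors = FALSE)
  }
  add("== pipeline report: %s ==", out_dir)
  tl <- read_art("turn_log.tsv")
  if (!is.null(tl) && nrow(tl)) {
    add("integration growth (turn: nodes / edges):")
    for (i in seq_len(nrow(tl))) {
      add("  turn %d (+%s): %d nodes, %d edges", tl$turn[i],
          tl$query_organism[i], tl$n_nodes[i], tl$n_edges[i])
    }
  }
  topo <- read_art("topology.tsv")
  if (!is.null(topo) && nrow(topo)) {
    add("topology of the largest component:")
    for (i in seq_len(nrow(topo))) {
      add("  %-16s nodes %4d edges %5d diameter %2s APL %5s CC %5s <k> %5s",
          topo$network[i], topo$n_nodes[i], topo$n_edges[i],
          format(topo$diameter[i]),
          format(round(topo$average_path_length[i], 2)),
          format(round(topo$clustering_coefficient[i], 3)),
          format(round(topo$average_degree[i], 2)))
    }
  }
  sd <- read_art("score_distribution.tsv")
  if (!is.null(sd) && nrow(sd)) {
    add("interaction score distribution:")
    for (i in which(sd$count > 0)) {
      add("  %-7s %5d (%5.1f%%)", sd$bin[i], sd$count[i], sd$percent[i])
    }
  }
  af <- read_art("assigned_functions.tsv")
  seeds <- read_art("signaling_seeds.tsv")
  if (!is.null(seeds)) {
    add("signaling: %d seed proteins, %d isolated", nrow(seeds),
        sum(seeds$isolated))
  }
  if (!is.null(af)) {
    add("function assignment: %d (protein, term) pairs for %d proteins",
        nrow(af), length(unique(af$protein)))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
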
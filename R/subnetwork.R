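#' Select the best homology hit per query
#'
#' Implements the first-hit rule used throughout the pipeline: for each
#' query, the first hit in file order with E-value strictly below the
#' cutoff is the homolog. Note this is the *first* passing hit, not the hit
#' with the lowest E-value; ties on rank are broken by lower E-value, then
#' higher bitscore, then lexicographic subject, so the selection is
#' deterministic on any input ordering.
#'
#' @param hits data.frame of hits as from [read_blast_tab()] (columns
#'   `query`, `subject`, `evalue`; optional `rank` and `bitscore`). If
#'   `rank` is absent, file (row) order is used.
#' @param evalue_max E-value cutoff; hits with `evalue < evalue_max` pass.
#' @return named character vector mapping each query with at least one
#'   passing hit to its selected subject.
#' @export
best_hits <- function(hits, evalue_max = 1e-5) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(setNames(character(0), character(0)))
  }
  h <- hits
  if (is.null(h$rank)) h$rank <- seq_len(nrow(h)) - 1L
  if (is.null(h$bitscore)) h$bitscore <- 0
  h <- h[h$evalue < evalue_max, , drop = FALSE]
  if (nrow(h) == 0L) return(setNames(character(0), character(0)))
  o <- order(h$query, h$rank, h$evalue, -h$bitscore, h$subject)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$query), , drop = FALSE]
  setNames(h$subject, h$query)
}

#' Invert a unigene-to-protein best-hit map
#'
#' Unigenes and proteins are not one-to-one: several unigenes may best-hit
#' the same protein, so the inverse is a multimap.
#'
#' @param best named character vector mapping unigene to protein, as from
#'   [best_hits()] on a unigene-vs-proteome search.
#' @return named list mapping protein to the character vector of unigenes
#'   that selected it.
#' @export
map_unigenes <- function(best) {
  if (length(best) == 0L) return(setNames(list(), character(0)))
  out <- split(names(best), unname(best))
  lapply(out, function(x) sort(unname(x)))
}

#' Construct a model-organism sub-network object
#'
#' @param organism organism name.
#' @param edges data.frame with columns `protein_a`, `protein_b` (unordered
#'   pairs; canonicalized and deduplicated here).
#' @param protein_to_unigenes named list mapping each protein to its
#'   unigenes (every node must have at least one).
#' @param stage evolutionary stage label: `"P"` (primitive), `"B"`
#'   (bilaterian) or `"V"` (vertebrate); may be `NA`.
#' @return object of class `pin_subnetwork` with fields `organism`,
#'   `stage`, `nodes`, `edges`, `protein_to_unigenes`.
#' @export
subnetwork <- function(organism, edges, protein_to_unigenes, stage = NA_character_) {
  stopifnot(is.character(organism), length(organism) == 1L)
  if (!is.na(stage) && !stage %in% c("P", "B", "V")) {
    stopf("stage must be one of P, B, V (got %s)", stage)
  }
  if (nrow(edges)) {
    edges <- collapse_pairs(edges$protein_a, edges$protein_b)[, c("protein_a", "protein_b")]
  } else {
    edges <- data.frame(protein_a = character(0), protein_b = character(0),
                        stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  missing_map <- nodes[!vapply(nodes, function(n)
    length(protein_to_unigenes[[n]] %||% character(0)) > 0, logical(1L))]
  if (length(missing_map)) {
    stopf("sub-network node(s) without a mapped unigene: %s",
          paste(head(missing_map, 5L), collapse = ", "))
  }
  structure(list(organism = organism, stage = stage, nodes = nodes,
                 edges = edges,
                 protein_to_unigenes = protein_to_unigenes[nodes]),
            class = "pin_subnetwork")
}

#' @export
print.pin_subnetwork <- function(x, ...) {
  cat(sprintf("<pin_subnetwork> %s (stage %s): %d proteins, %d interactions, %d unigenes\n",
              x$organism, x$stage, length(x$nodes), nrow(x$edges),
              length(unique(unlist(x$protein_to_unigenes)))))
  invisible(x)
}

#' Build a model-organism-based interaction sub-network
#'
#' An interaction of the model organism is kept if and only if both of its
#' proteins are matched by at least one unigene of the target organism; the
#' kept proteins and interactions form the model-organism-based
#' sub-network. Proteins matched by a unigene but participating in no kept
#' interaction are not nodes of the sub-network.
#'
#' @param records interaction data.frame (columns `protein_a`,
#'   `protein_b`), e.g. from [read_interactions()] after name
#'   normalization.
#' @param protein_to_unigenes named list from [map_unigenes()].
#' @param organism organism name.
#' @param stage evolutionary stage label (see [subnetwork()]).
#' @return a `pin_subnetwork`; its attribute `input_counts` records the
#'   number of input interactions and input proteins for summary ratios.
#' @export
build_subnetwork <- function(records, protein_to_unigenes, organism,
                             stage = NA_character_) {
  mapped <- names(protein_to_unigenes)[lengths(protein_to_unigenes) > 0L]
  keep <- records$protein_a %in% mapped & records$protein_b %in% mapped
  sn <- subnetwork(organism, records[keep, , drop = FALSE],
                   protein_to_unigenes, stage)
  attr(sn, "input_counts") <- list(
    n_input_interactions = nrow(records),
    n_input_proteins = length(unique(c(records$protein_a, records$protein_b))))
  sn
}

#' Summary table for a list of sub-networks
#'
#' One row per sub-network with unigene, protein and interaction counts,
#' plus interaction and protein retention ratios relative to the input
#' interaction list when [build_subnetwork()] recorded them.
#'
#' @param subnetworks list of `pin_subnetwork` objects.
#' @return data.frame.
#' @export
subnetwork_summary <- function(subnetworks) {
  rows <- lapply(subnetworks, function(sn) {
    ic <- attr(sn, "input_counts")
    data.frame(organism = sn$organism, stage = sn$stage,
               n_unigenes = length(unique(unlist(sn$protein_to_unigenes))),
               n_proteins = length(sn$nodes),
               n_interactions = nrow(sn$edges),
               interaction_retention = if (is.null(ic) || ic$n_input_interactions == 0)
                 NA_real_ else nrow(sn$edges) / ic$n_input_interactions,
               protein_retention = if (is.null(ic) || ic$n_input_proteins == 0)
                 NA_real_ else length(sn$nodes) / ic$n_input_proteins,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
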
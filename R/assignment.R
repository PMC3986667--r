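## Neighbor-majority function assignment: a modified guilt-by-association
## rule. A GO term is copied to an unclassified protein when the annotated
## neighbours carrying it make up strictly more than a threshold fraction
## (default 25%); a protein with exactly one annotated neighbour inherits
## all of that neighbour's terms. Rounds are synchronous (every assignment
## in a round is computed from the previous round's state) and iterate to a
## fixpoint, so newly classified proteins can seed later rounds.

#' Assign GO terms to unclassified proteins from their neighbours
#'
#' @param network any network accepted by [pin_graph()].
#' @param annotations named list protein -> GO term ids; proteins with a
#'   non-empty set are the initially classified proteins.
#' @param threshold support fraction that must be strictly exceeded for a
#'   term to be assigned (default 0.25, in (0, 1)).
#' @param denominator `"annotated"` (default): the support fraction divides
#'   by the number of *annotated* neighbours; `"all"`: by the total number
#'   of neighbours.
#' @param dag optional `go_dag`; with `propagate = TRUE` annotations are
#'   closed under is_a ancestors before counting.
#' @param propagate see `dag`.
#' @return object of class `pin_assignment`: list with `assigned` (named
#'   list protein -> newly assigned terms), `rounds` (number of productive
#'   rounds before the fixpoint) and `provenance` (data.frame with one row
#'   per protein-term assignment: supporting fraction, number of annotated
#'   neighbours, round).
#' @export
assign_functions <- function(network, annotations, threshold = 0.25,
                             denominator = c("annotated", "all"),
                             dag = NULL, propagate = FALSE) {
  denominator <- match.arg(denominator)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold >= 1) {
    stopf("threshold must be a fraction strictly between 0 and 1")
  }
  if (propagate) {
    if (is.null(dag)) stopf("propagate = TRUE requires a dag")
    annotations <- propagate_annotations(annotations, dag)
  }
  g <- igraph::simplify(pin_graph(network))
  nodes <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, nodes), function(v) v$name)
  names(adj) <- nodes
  ann <- annotations[lengths(annotations) > 0L]
  ann <- ann[names(ann) %in% nodes]
  classified <- names(ann)
  unclassified <- setdiff(nodes, classified)

  assigned <- list()
  prov <- list()
  rounds <- 0L
  repeat {
    new <- list()
    for (u in unclassified) {
      nb_ann <- intersect(adj[[u]], classified)
      if (length(nb_ann) == 0L) next
      if (length(nb_ann) == 1L) {
        terms <- sort(unique(ann[[nb_ann]]))
        fracs <- rep(1, length(terms))
      } else {
        tally <- table(unlist(lapply(ann[nb_ann], unique),
                              use.names = FALSE))
        denom <- if (denominator == "annotated") length(nb_ann)
                 else length(adj[[u]])
        fracs_all <- as.numeric(tally) / denom
        pass <- fracs_all > threshold
        terms <- sort(names(tally)[pass])
        fracs <- fracs_all[pass][order(names(tally)[pass])]
      }
      if (length(terms) == 0L) next
      new[[u]] <- terms
      prov[[length(prov) + 1L]] <- data.frame(
        protein = u, term = terms, support_fraction = fracs,
        n_annotated_neighbors = length(nb_ann), round = rounds + 1L,
        stringsAsFactors = FALSE)
    }
    if (length(new) == 0L) break
    rounds <- rounds + 1L
    assigned <- c(assigned, new)
    ann[names(new)] <- new            # synchronous: applied after the round
    classified <- c(classified, names(new))
    unclassified <- setdiff(unclassified, names(new))
  }
  provenance <- if (length(prov)) {
    do.call(rbind, c(prov, list(make.row.names = FALSE)))
  } else {
    data.frame(protein = character(0), term = character(0),
               support_fraction = numeric(0),
               n_annotated_neighbors = integer(0), round = integer(0),
               stringsAsFactors = FALSE)
  }
  structure(list(assigned = assigned[sort(names(assigned))],
                 rounds = rounds, provenance = provenance),
            class = "pin_assignment")
}

#' @export
print.pin_assignment <- function(x, ...) {
  cat(sprintf("<pin_assignment> %d proteins assigned %d terms in %d round(s)\n",
              length(x$assigned), nrow(x$provenance), x$rounds))
  invisible(x)
}

#' Distribution of assignments over GO depth
#'
#' Counts (protein, term) assignment pairs per depth of the assigned term
#' in the GO DAG (root depth 1; deeper terms are more specific).
#'
#' @param result a `pin_assignment` from [assign_functions()].
#' @param dag the `go_dag` the terms belong to.
#' @return data.frame with columns `depth`, `n_assignments`.
#' @export
depth_distribution <- function(result, dag) {
  stopifnot(inherits(result, "pin_assignment"))
  terms <- unlist(result$assigned, use.names = FALSE)
  if (length(terms) == 0L) {
    return(data.frame(depth = integer(0), n_assignments = integer(0)))
  }
  depths <- go_depths(dag)
  bad <- setdiff(unique(terms), names(depths))
  if (length(bad)) {
    stopf("assigned term(s) absent from the ontology: %s",
          paste(head(bad, 5L), collapse = ", "))
  }
  tab <- table(depths[terms])
  data.frame(depth = as.integer(names(tab)),
             n_assignments = as.integer(tab), stringsAsFactors = FALSE)
}

#' Hide a fraction of annotations for recovery evaluation
#'
#' @param annotations named list protein -> GO term ids.
#' @param fraction fraction of annotated proteins whose annotations are
#'   hidden.
#' @param seed RNG seed for the sample of hidden proteins.
#' @return list with `visible` (annotations minus the hidden proteins) and
#'   `hidden` (the held-out truth).
#' @export
hide_annotations <- function(annotations, fraction, seed = 1L) {
  stopifnot(is_prob(fraction))
  ann <- annotations[lengths(annotations) > 0L]
  n_hide <- floor(fraction * length(ann))
  set.seed(seed)
  hidden_ids <- sort(sample(names(ann), n_hide))
  list(visible = ann[setdiff(names(ann), hidden_ids)],
       hidden = ann[hidden_ids])
}

#' Precision and recall of recovered hidden annotations
#'
#' Compares the (protein, term) pairs assigned to held-out proteins with
#' the hidden truth.
#'
#' @param result a `pin_assignment` computed from the visible annotations.
#' @param truth named list of the hidden proteins' true term sets (e.g. the
#'   `hidden` element of [hide_annotations()]).
#' @return list with `precision`, `recall` (NA when undefined),
#'   `n_hidden_proteins`, `n_true_pairs`, `n_predicted_pairs`.
#' @export
recovery_evaluation <- function(result, truth) {
  stopifnot(inherits(result, "pin_assignment"))
  truth <- truth[lengths(truth) > 0L]
  pair_set <- function(lst) {
    if (length(lst) == 0L) return(character(0))
    unlist(lapply(names(lst), function(p) paste(p, lst[[p]], sep = "\t")),
           use.names = FALSE)
  }
  true_pairs <- pair_set(truth)
  pred_pairs <- pair_set(result$assigned[intersect(names(result$assigned),
                                                   names(truth))])
  list(precision = if (length(pred_pairs))
         mean(pred_pairs %in% true_pairs) else NA_real_,
       recall = if (length(true_pairs))
         mean(true_pairs %in% pred_pairs) else NA_real_,
       n_hidden_proteins = length(truth),
       n_true_pairs = length(true_pairs),
       n_predicted_pairs = length(pred_pairs))
}
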
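#' Construct a GO DAG object
#'
#' A `go_dag` holds GO terms connected by `is_a` edges. The structure is
#' validated on construction: every parent must be a known term and the
#' `is_a` relation must be acyclic (GO is a directed acyclic graph).
#'
#' @param terms named list; each element is a list with fields `id`, `name`,
#'   `namespace` and `parents` (character vector of `is_a` parent ids,
#'   empty for roots).
#' @return an object of class `go_dag` with fields `terms` (the validated
#'   list) and `roots` (ids with no parents).
#' @export
go_dag <- function(terms) {
  if (length(terms) == 0L) {
    return(structure(list(terms = list(), roots = character(0)),
                     class = "go_dag"))
  }
  ids <- unname(vapply(terms, function(t) t$id, character(1L)))
  names(terms) <- ids
  for (t in terms) {
    bad <- setdiff(t$parents, ids)
    if (length(bad)) {
      stopf("term %s has unknown is_a parent(s): %s", t$id,
            paste(bad, collapse = ", "))
    }
  }
  ## Kahn's algorithm: if a topological order does not exhaust the terms,
  ## the is_a relation contains a cycle.
  n_parents <- vapply(terms, function(t) length(t$parents), integer(1L))
  children <- term_children(terms)
  queue <- ids[n_parents == 0L]
  seen <- 0L
  remaining <- n_parents
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[cur]] %||% character(0)) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) {
    stopf("is_a relation contains a cycle (%d of %d terms unreachable from roots)",
          length(terms) - seen, length(terms))
  }
  roots <- ids[n_parents == 0L]
  if (length(roots) == 0L) stopf("ontology has no root term")
  structure(list(terms = terms, roots = roots), class = "go_dag")
}

term_children <- function(terms) {
  children <- setNames(vector("list", length(terms)), names(terms))
  for (t in terms) {
    for (p in t$parents) children[[p]] <- c(children[[p]], t$id)
  }
  children
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d root(s): %s\n", length(x$terms),
              length(x$roots), paste(x$roots, collapse = ", ")))
  invisible(x)
}

check_term <- function(dag, term) {
  if (!term %in% names(dag$terms)) stopf("unknown GO term: %s", term)
}

#' All is_a ancestors of a term
#'
#' @param dag a `go_dag`.
#' @param term a term id present in `dag`.
#' @return character vector of ancestor ids (the term itself excluded).
#' @export
go_ancestors <- function(dag, term) {
  check_term(dag, term)
  anc <- character(0)
  frontier <- dag$terms[[term]]$parents
  while (length(frontier)) {
    anc <- union(anc, frontier)
    frontier <- unique(unlist(lapply(frontier,
                                     function(p) dag$terms[[p]]$parents)))
    frontier <- setdiff(frontier, anc)
  }
  sort(anc)
}

#' Depth of every term in the GO DAG
#'
#' Depth is the length of the shortest is_a path from a root, with roots at
#' depth 1 (a multi-parent term takes the minimum over its parents).
#'
#' @param dag a `go_dag`.
#' @return named integer vector of depths, one per term.
#' @export
go_depths <- function(dag) {
  depths <- setNames(rep(NA_integer_, length(dag$terms)), names(dag$terms))
  depths[dag$roots] <- 1L
  frontier <- dag$roots
  children <- term_children(dag$terms)
  d <- 1L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(children[frontier])),
                   names(depths)[!is.na(depths)])
    depths[nxt] <- d
    frontier <- nxt
  }
  depths
}

#' Depth of one GO term
#'
#' @inheritParams go_ancestors
#' @return integer depth (root = 1; shortest is_a path for multi-parent
#'   terms).
#' @export
go_depth <- function(dag, term) {
  check_term(dag, term)
  unname(go_depths(dag)[term])
}

#' Close an annotation table under is_a ancestors
#'
#' True-path completion: a protein annotated with a term is implicitly
#' annotated with every ancestor of that term, so e.g. any descendant of the
#' "signaling" term qualifies as signaling-annotated after propagation.
#'
#' @param annotations named list mapping protein id to a character vector of
#'   GO term ids.
#' @param dag a `go_dag` containing every annotated term.
#' @return the annotation list with each term set closed under ancestors.
#' @export
propagate_annotations <- function(annotations, dag) {
  all_terms <- unique(unlist(annotations))
  bad <- setdiff(all_terms, names(dag$terms))
  if (length(bad)) {
    stopf("annotation uses term(s) absent from the ontology: %s",
          paste(head(bad, 5L), collapse = ", "))
  }
  anc <- lapply(setNames(all_terms, all_terms),
                function(t) go_ancestors(dag, t))
  lapply(annotations, function(ts) {
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
}
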
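#' Read a protein interaction list
#'
#' Reads PINA-style identifier pairs. The `mitab_lite` dialect accepts lines
#' such as `uniprotkb:Q7PLP5-uniprotkb:A1Z8V7` or two tab-separated
#' identifier columns; the `tsv` dialect takes the first two tab-separated
#' columns. `uniprotkb:` prefixes are stripped, pairs are unordered
#' ((a,b) and (b,a) collapse to one record with a duplicate count), and
#' self-interactions are retained but flagged.
#'
#' @param path path to the interaction file.
#' @param dialect `"mitab_lite"` (default) or `"tsv"`.
#' @return data.frame with columns `protein_a`, `protein_b` (canonical
#'   unordered pair, `protein_a <= protein_b`), `n_records` (how many raw
#'   lines collapsed into the pair) and `self_interaction`.
#' @export
read_interactions <- function(path, dialect = c("mitab_lite", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      n_records = integer(0), self_interaction = logical(0),
                      stringsAsFactors = FALSE))
  }
  parse_line <- function(line, n) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L && dialect == "mitab_lite") {
      ## PINA single-column form: "uniprotkb:A-uniprotkb:B"; identifiers may
      ## themselves contain "-" (CIR-1, Vha36-2), so split only at the
      ## boundary in front of a uniprotkb: prefix.
      fields <- strsplit(line, "-\\s*(?=uniprotkb:)", perl = TRUE)[[1L]]
    }
    if (length(fields) < 2L) {
      stopf("line %d: cannot parse interaction record: %s", n, line)
    }
    ids <- sub("^uniprotkb:", "", trimws(fields[1:2]))
    if (any(!nzchar(ids))) {
      stopf("line %d: empty identifier after prefix stripping", n)
    }
    ids
  }
  parsed <- mapply(parse_line, lines, lineno, SIMPLIFY = FALSE)
  a <- vapply(parsed, `[`, character(1L), 1L)
  b <- vapply(parsed, `[`, character(1L), 2L)
  collapse_pairs(a, b)
}

collapse_pairs <- function(a, b) {
  df <- canonicalize_pairs(unname(a), unname(b))
  key <- paste(df$protein_a, df$protein_b, sep = "\t")
  counts <- table(key)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$n_records <- as.integer(counts[key[first]])
  out$self_interaction <- out$protein_a == out$protein_b
  rownames(out) <- NULL
  out
}

#' Replace protein IDs by protein names in interaction records
#'
#' PINA records sometimes show the same protein as a Uniprot ID in one
#' interaction and as a gene/protein name in another (e.g. A1Z8V7 vs
#' Vha36-2). Where a name is known for an ID, the name is used; identifiers
#' without a known name are kept as-is. Pairs are re-canonicalized and
#' re-collapsed after replacement, since renaming can make records coincide.
#'
#' @param records interaction data.frame as returned by
#'   [read_interactions()].
#' @param id_to_name named character vector mapping protein IDs to names;
#'   may be partial.
#' @return list with `records` (normalized data.frame) and `n_replaced`
#'   (number of distinct identifiers replaced).
#' @export
normalize_protein_names <- function(records, id_to_name) {
  if (length(id_to_name) == 0L || nrow(records) == 0L) {
    return(list(records = records, n_replaced = 0L))
  }
  replace_col <- function(x) {
    hit <- x %in% names(id_to_name)
    x[hit] <- unname(id_to_name[x[hit]])
    x
  }
  present <- unique(c(records$protein_a, records$protein_b))
  replaced_ids <- intersect(present, names(id_to_name))
  ## An "id" already written identically to its name is not a replacement.
  replaced_ids <- replaced_ids[id_to_name[replaced_ids] != replaced_ids]
  a <- replace_col(records$protein_a)
  b <- replace_col(records$protein_b)
  out <- canonicalize_pairs(a, b)
  key <- paste(out$protein_a, out$protein_b, sep = "\t")
  counts <- tapply(records$n_records, key, sum)
  first <- !duplicated(key)
  out <- out[first, , drop = FALSE]
  out$n_records <- as.integer(counts[key[first]])
  out$self_interaction <- out$protein_a == out$protein_b
  rownames(out) <- NULL
  list(records = out, n_replaced = length(replaced_ids))
}

blast_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6 style) hit file
#'
#' Hits are kept in file order and a 0-based `rank` is assigned per query in
#' that order; duplicate (query, subject) lines are kept as distinct hits.
#'
#' @param path path to a 12-column tab-separated BLAST output file.
#' @return data.frame with columns `query`, `subject`, `pident`, `length`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore`, `rank`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  empty <- data.frame(query = character(0), subject = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) return(empty)
  df <- read.delim(path, header = FALSE, col.names = blast_columns,
                   colClasses = c("character", "character", rep("character", 10L)),
                   stringsAsFactors = FALSE)
  num <- suppressWarnings(as.numeric(df$evalue))
  if (anyNA(num)) {
    stopf("non-numeric evalue at line %d", which(is.na(num))[1L])
  }
  out <- data.frame(query = df$qseqid, subject = df$sseqid,
                    pident = as.numeric(df$pident),
                    length = as.integer(df$length),
                    mismatch = as.integer(df$mismatch),
                    gapopen = as.integer(df$gapopen),
                    qstart = as.integer(df$qstart),
                    qend = as.integer(df$qend),
                    sstart = as.integer(df$sstart),
                    send = as.integer(df$send),
                    evalue = num,
                    bitscore = as.numeric(df$bitscore),
                    stringsAsFactors = FALSE)
  out$rank <- as.integer(ave(seq_len(nrow(out)), out$query,
                             FUN = seq_along) - 1L)
  out
}

#' Read an OBO ontology file into a GO DAG
#'
#' Parses `[Term]` stanzas with `id`, `name`, `namespace` and `is_a` tags
#' (the subset of OBO the pipeline needs). Obsolete terms are skipped and
#' cyclic input is rejected.
#'
#' @param path path to the OBO file.
#' @return a [go_dag()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(terms)
    terms[[cur$id]] <- list(id = cur$id, name = cur$name %||% cur$id,
                            namespace = cur$namespace %||% "biological_process",
                            parents = cur$parents %||% character(0))
    terms
  }
  in_term <- FALSE
  for (line in lines) {
    line <- trimws(line)
    if (line == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(0))
      in_term <- TRUE
      next
    }
    if (startsWith(line, "[")) {          # [Typedef] etc.
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(line)) next
    if (startsWith(line, "id: ")) cur$id <- sub("^id: *", "", line)
    else if (startsWith(line, "name: ")) cur$name <- sub("^name: *", "", line)
    else if (startsWith(line, "namespace: ")) {
      cur$namespace <- sub("^namespace: *", "", line)
    } else if (startsWith(line, "is_a: ")) {
      parent <- sub("^is_a: *", "", line)
      parent <- trimws(strsplit(parent, "!", fixed = TRUE)[[1L]][1L])
      cur$parents <- c(cur$parents, parent)
    } else if (startsWith(line, "is_obsolete: true")) cur$obsolete <- TRUE
  }
  terms <- flush(cur, terms)
  go_dag(terms)
}

#' Write a GO DAG as an OBO-lite file
#'
#' @param dag a [go_dag()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (id in sort(names(dag$terms))) {
    t <- dag$terms[[id]]
    out <- c(out, "[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
             paste0("namespace: ", t$namespace))
    for (p in sort(t$parents)) {
      out <- c(out, paste0("is_a: ", p, " ! ", dag$terms[[p]]$name))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

network_tsv_columns <- c("record_type", "id_a", "id_b", "organisms",
                         "unigenes", "members", "scores", "total")

#' Write / read an integrated network as TSV
#'
#' The file is a single TSV with a `record_type` column: `node` rows carry
#' the node ledger (source organisms, unigenes, merged member proteins and
#' the per-turn point-matching scores), `edge` rows carry the edge ledger
#' (per-turn edge-matching scores and the total interaction score) and
#' `turn` rows preserve the integration turn log. The round trip is
#' lossless.
#'
#' @param network a `pin_integrated` network (see [integrate_all()]).
#' @param path output path.
#' @return `path` invisibly (write) / the reconstructed network (read).
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "pin_integrated"))
  join <- function(x) paste(sort(x), collapse = ",")
  join_scores <- function(s) paste(as.integer(s), collapse = ",")
  node_names <- sort(names(network$nodes))
  node_rows <- lapply(node_names, function(nm) {
    n <- network$nodes[[nm]]
    data.frame(record_type = "node", id_a = nm, id_b = "",
               organisms = join(n$organisms), unigenes = join(n$unigenes),
               members = join(n$members), scores = join_scores(n$scores),
               total = sum(n$scores), stringsAsFactors = FALSE)
  })
  edge_keys <- sort(names(network$edges))
  edge_rows <- lapply(edge_keys, function(k) {
    e <- network$edges[[k]]
    data.frame(record_type = "edge", id_a = e$a, id_b = e$b,
               organisms = join(e$organisms), unigenes = "", members = "",
               scores = join_scores(e$scores),
               total = edge_total_score(network, k),
               stringsAsFactors = FALSE)
  })
  turn_rows <- lapply(seq_len(nrow(network$turn_log)), function(i) {
    tl <- network$turn_log[i, ]
    data.frame(record_type = "turn", id_a = as.character(tl$turn),
               id_b = tl$query_organism, organisms = "", unigenes = "",
               members = "", scores = join_scores(c(tl$n_nodes, tl$n_edges)),
               total = NA_integer_, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(node_rows, edge_rows, turn_rows,
                         list(make.row.names = FALSE)))
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(character(0)),
                                     length(network_tsv_columns)),
                                 network_tsv_columns))
  }
  df <- rbind(data.frame(record_type = "meta", id_a = "n_turns", id_b = "",
                         organisms = "", unigenes = "", members = "",
                         scores = as.character(network$n_turns),
                         total = NA_integer_, stringsAsFactors = FALSE), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (!identical(names(df), network_tsv_columns)) {
    stopf("schema mismatch: expected columns %s",
          paste(network_tsv_columns, collapse = ", "))
  }
  split_ids <- function(x) if (nzchar(x)) strsplit(x, ",", fixed = TRUE)[[1L]] else character(0)
  split_scores <- function(x) {
    if (!nzchar(x)) return(integer(0))
    as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
  }
  meta <- df[df$record_type == "meta" & df$id_a == "n_turns", , drop = FALSE]
  if (nrow(meta) != 1L) stopf("schema mismatch: missing n_turns meta row")
  n_turns <- as.integer(meta$scores)
  nodes <- list()
  for (i in which(df$record_type == "node")) {
    nodes[[df$id_a[i]]] <- list(organisms = split_ids(df$organisms[i]),
                                unigenes = split_ids(df$unigenes[i]),
                                members = split_ids(df$members[i]),
                                scores = split_scores(df$scores[i]))
  }
  edges <- list()
  for (i in which(df$record_type == "edge")) {
    edges[[edge_key(df$id_a[i], df$id_b[i])]] <-
      list(a = df$id_a[i], b = df$id_b[i],
           organisms = split_ids(df$organisms[i]),
           scores = split_scores(df$scores[i]))
  }
  ti <- which(df$record_type == "turn")
  turn_log <- empty_turn_log()
  if (length(ti)) {
    counts <- lapply(df$scores[ti], split_scores)
    turn_log <- data.frame(turn = as.integer(df$id_a[ti]),
                           query_organism = df$id_b[ti],
                           n_nodes = vapply(counts, `[`, integer(1L), 1L),
                           n_edges = vapply(counts, `[`, integer(1L), 2L),
                           stringsAsFactors = FALSE)
    turn_log <- turn_log[order(turn_log$turn), , drop = FALSE]
    rownames(turn_log) <- NULL
  }
  structure(list(n_turns = n_turns, nodes = nodes, edges = edges,
                 turn_log = turn_log), class = "pin_integrated")
}
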
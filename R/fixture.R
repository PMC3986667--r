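## On-disk fixture layout for a synthetic universe:
##   organisms.tsv                 organism, stage, retention_prob, order
##   interactions/<org>.tsv        MITAB-lite identifier pairs
##   blastx/<org>.tsv              unigene-vs-proteome hits (outfmt 6)
##   blastp/<qorg>__<torg>.tsv     cross-organism protein hits (outfmt 6)
##   ontology.obo                  OBO-lite GO DAG
##   annotations.tsv               protein, go_id (one row per pair)
##   pathways.tsv                  pathway, protein
##   manifest.yaml                 relative paths + md5 checksums

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  for (col in names(df)[num]) {
    ## 17 significant digits round-trip doubles exactly through read.delim.
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic universe to disk as plain-text fixture files
#'
#' Emits MITAB-lite interaction files, BLAST-tabular homology hit files, an
#' OBO-lite ontology, annotation/pathway/organism tables and a YAML
#' manifest with md5 checksums. Output is byte-identical across runs for
#' the same universe.
#'
#' @param universe a `pin_universe`.
#' @param directory output directory (created if needed).
#' @return data.frame manifest (columns `path`, `md5`), invisibly; also
#'   written as `manifest.yaml`.
#' @export
write_fixture <- function(universe, directory) {
  stopifnot(inherits(universe, "pin_universe"))
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory: %s", directory)
  for (sub in c("interactions", "blastx", "blastp")) {
    dir.create(file.path(directory, sub), showWarnings = FALSE)
  }
  orgs <- universe$organisms
  files <- character(0)

  org_df <- data.frame(organism = orgs$organism, stage = orgs$stage,
                       retention_prob = orgs$retention_prob,
                       order = seq_len(nrow(orgs)), stringsAsFactors = FALSE)
  write_tsv(org_df, file.path(directory, "organisms.tsv"))
  files <- c(files, "organisms.tsv")

  for (org in orgs$organism) {
    rel <- file.path("interactions", paste0(org_filename(org), ".tsv"))
    edges <- universe$interactions[[org]]
    writeLines(if (nrow(edges)) paste0("uniprotkb:", edges$protein_a, "\t",
                                       "uniprotkb:", edges$protein_b)
               else character(0),
               file.path(directory, rel))
    files <- c(files, rel)

    rel <- file.path("blastx", paste0(org_filename(org), ".tsv"))
    hits <- universe$unigene_hits[[org]]
    write.table(format_blast(hits), file.path(directory, rel), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- c(files, rel)
  }

  for (key in sort(names(universe$cross_hits))) {
    qt <- strsplit(key, "->", fixed = TRUE)[[1L]]
    rel <- file.path("blastp", paste0(org_filename(qt[1L]), "__",
                                      org_filename(qt[2L]), ".tsv"))
    write.table(format_blast(universe$cross_hits[[key]]),
                file.path(directory, rel), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    files <- c(files, rel)
  }

  write_obo(universe$dag, file.path(directory, "ontology.obo"))
  files <- c(files, "ontology.obo")

  ann <- universe$annotations
  ann_df <- if (length(ann)) {
    data.frame(protein = rep(names(ann), lengths(ann)),
               go_id = unlist(ann, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(protein = character(0), go_id = character(0),
               stringsAsFactors = FALSE)
  }
  ann_df <- ann_df[order(ann_df$protein, ann_df$go_id, method = "radix"), ,
                   drop = FALSE]
  write_tsv(ann_df, file.path(directory, "annotations.tsv"))
  files <- c(files, "annotations.tsv")

  ## Pathway membership written with first-organism protein ids (pathway
  ## families are always present there).
  first_org <- orgs$organism[1L]
  pw <- data.frame(pathway = rep("planted", length(universe$pathway_families)),
                   protein = universe$proteins[universe$pathway_families,
                                               first_org],
                   stringsAsFactors = FALSE)
  pw <- pw[!is.na(pw$protein), , drop = FALSE]
  pw <- pw[order(pw$protein, method = "radix"), , drop = FALSE]
  write_tsv(pw, file.path(directory, "pathways.tsv"))
  files <- c(files, "pathways.tsv")

  manifest <- data.frame(path = files,
                         md5 = unname(md5sum(file.path(directory, files))),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$path, method = "radix"), , drop = FALSE]
  rownames(manifest) <- NULL
  yaml::write_yaml(
    list(files = lapply(seq_len(nrow(manifest)), function(i)
      list(path = manifest$path[i], md5 = manifest$md5[i]))),
    file.path(directory, "manifest.yaml"))
  invisible(manifest)
}

format_blast <- function(hits) {
  df <- hits[, setdiff(names(hits), "rank"), drop = FALSE]
  for (col in c("pident", "evalue", "bitscore")) {
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  }
  df
}

#' Read a fixture directory back into memory
#'
#' Uses the package readers ([read_interactions()], [read_blast_tab()],
#' [read_obo()]) on the layout written by [write_fixture()].
#'
#' @param directory fixture directory.
#' @return list with `organisms`, `stages`, `interactions`,
#'   `unigene_hits`, `cross_hits`, `dag`, `annotations`, `pathways`.
#' @export
read_fixture <- function(directory) {
  orgs_path <- file.path(directory, "organisms.tsv")
  if (!file.exists(orgs_path)) stopf("not a fixture directory: %s", directory)
  orgs <- read.delim(orgs_path, stringsAsFactors = FALSE)
  orgs <- orgs[order(orgs$order), , drop = FALSE]
  interactions <- list()
  unigene_hits <- list()
  for (org in orgs$organism) {
    interactions[[org]] <- read_interactions(
      file.path(directory, "interactions", paste0(org_filename(org), ".tsv")))
    unigene_hits[[org]] <- read_blast_tab(
      file.path(directory, "blastx", paste0(org_filename(org), ".tsv")))
  }
  cross_hits <- list()
  for (qorg in orgs$organism) {
    for (torg in orgs$organism) {
      if (qorg == torg) next
      path <- file.path(directory, "blastp",
                        paste0(org_filename(qorg), "__",
                               org_filename(torg), ".tsv"))
      if (file.exists(path)) {
        cross_hits[[paste0(qorg, "->", torg)]] <- read_blast_tab(path)
      }
    }
  }
  dag <- read_obo(file.path(directory, "ontology.obo"))
  ann_df <- read.delim(file.path(directory, "annotations.tsv"),
                       colClasses = "character", stringsAsFactors = FALSE)
  annotations <- lapply(split(ann_df$go_id, ann_df$protein),
                        function(x) sort(unique(x)))
  pw_path <- file.path(directory, "pathways.tsv")
  pathways <- list()
  if (file.exists(pw_path)) {
    pw <- read.delim(pw_path, colClasses = "character",
                     stringsAsFactors = FALSE)
    if (nrow(pw)) pathways <- lapply(split(pw$protein, pw$pathway), sort)
  }
  list(organisms = orgs, stages = setNames(orgs$stage, orgs$organism),
       interactions = interactions, unigene_hits = unigene_hits,
       cross_hits = cross_hits, dag = dag, annotations = annotations,
       pathways = pathways)
}
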
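`%||%` <- function(x, y) if (is.null(x)) y else x

## Canonical key for an unordered protein pair. Identifiers never contain
## tab characters (enforced by the readers), so "\t" is a safe separator.
edge_key <- function(a, b) {
  if (a <= b) paste(a, b, sep = "\t") else paste(b, a, sep = "\t")
}

sorted_pair <- function(a, b) {
  if (a <= b) c(a, b) else c(b, a)
}

## Canonicalize an edge data.frame to unordered (protein_a <= protein_b).
canonicalize_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

## Short uppercase code for an organism name, e.g. "D.melanogaster" -> "DME".
org_code <- function(name) {
  parts <- strsplit(name, "[^A-Za-z]+")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return("ORG")
  if (length(parts) >= 2L) {
    toupper(paste0(substr(parts[1L], 1L, 1L),
                   substr(parts[length(parts)], 1L, 2L)))
  } else {
    toupper(substr(parts[1L], 1L, 3L))
  }
}

org_codes <- function(names) {
  codes <- vapply(names, org_code, character(1L))
  dup <- duplicated(codes)
  if (any(dup)) codes[dup] <- paste0(codes[dup], seq_len(sum(dup)))
  unname(codes)
}

## File-system-safe version of an organism name.
org_filename <- function(name) gsub("[^A-Za-z0-9._-]+", "_", name)
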
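#' Relation keys
#'
#' A relation block between entity types `a` and `b` is keyed `"a~b"`.
#'
#' @param source_type,target_type Entity type labels.
#' @return A single string key.
#' @export
relation_key <- function(source_type, target_type) {
  paste(source_type, target_type, sep = "~")
}

split_relation_key <- function(key) {
  parts <- strsplit(key, "~", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) {
    abort(sprintf("malformed relation key '%s' (expected 'source~target').", key))
  }
  parts
}

# Attach relation metadata to a plain matrix.
as_relation <- function(values, source, target) {
  values <- as.matrix(values)
  if (nrow(values) != length(source) || ncol(values) != length(target)) {
    abort(sprintf(
      "relation %s~%s has shape %dx%d but catalogs have sizes %d and %d.",
      catalog_type(source), catalog_type(target),
      nrow(values), ncol(values), length(source), length(target)
    ))
  }
  if (!all(is.finite(values))) {
    abort("relation matrix contains non-finite values.")
  }
  if (any(values < 0)) {
    abort("relation matrix contains negative values; entries must be >= 0.")
  }
  dimnames(values) <- list(as.character(source), as.character(target))
  attr(values, "source_type") <- catalog_type(source)
  attr(values, "target_type") <- catalog_type(target)
  values
}

#' Read a TSV edge list
#'
#' Edge lists have two or three tab-separated columns:
#' `source_id<TAB>target_id[<TAB>weight]`. Lines starting with `#` are
#' ignored. A missing weight column defaults to 1.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `source_id`, `target_id`, `weight`.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("edge-list file '%s' does not exist.", path))
  }
  edges <- readr::read_tsv(
    path,
    col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(edges) == 0L) {
    return(tibble(source_id = character(), target_id = character(), weight = double()))
  }
  if (!ncol(edges) %in% c(2L, 3L)) {
    abort(sprintf("edge list '%s' must have 2 or 3 columns, found %d.", path, ncol(edges)))
  }
  out <- tibble(
    source_id = edges[[1L]],
    target_id = edges[[2L]],
    weight = if (ncol(edges) == 3L) as.numeric(edges[[3L]]) else 1
  )
  if (anyNA(out$weight)) {
    abort(sprintf("edge list '%s' has a non-numeric weight column.", path))
  }
  out
}

#' Build a relation matrix from an edge table
#'
#' Every listed pair gets its weight (1 when absent); all other cells are 0.
#' Repeated identical edges collapse to one entry with a warning — public
#' interaction databases commonly contain duplicates.
#'
#' @param edges A tibble as returned by [read_edges()], or any data frame
#'   with columns `source_id`, `target_id` and optionally `weight`.
#' @param source,target [entity_catalog()]s for the rows and columns.
#' @return A numeric matrix of size `length(source) x length(target)` with
#'   `source_type`/`target_type` attributes and catalog dimnames.
#' @export
relation_from_edges <- function(edges, source, target) {
  edges <- as_tibble(edges)
  if (!all(c("source_id", "target_id") %in% names(edges))) {
    abort("`edges` must have columns source_id and target_id.")
  }
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, nrow(edges))
  if (any(w < 0 | w > 1)) {
    bad <- which(w < 0 | w > 1)[1L]
    abort(sprintf("edge %d has weight %g outside [0, 1].", bad, w[bad]))
  }
  ri <- integer(0)
  ci <- integer(0)
  if (nrow(edges) > 0L) {
    for (row in which(is.na(match(edges$source_id, source)))) {
      abort(sprintf(
        "edge %d names unknown %s identifier '%s'.",
        row, catalog_type(source), edges$source_id[row]
      ))
    }
    for (row in which(is.na(match(edges$target_id, target)))) {
      abort(sprintf(
        "edge %d names unknown %s identifier '%s'.",
        row, catalog_type(target), edges$target_id[row]
      ))
    }
    ri <- match(edges$source_id, source)
    ci <- match(edges$target_id, target)
    dup <- duplicated(paste(ri, ci))
    if (any(dup)) {
      warn(sprintf("%d duplicate edge(s) collapsed to single entries.", sum(dup)))
      ri <- ri[!dup]
      ci <- ci[!dup]
      w <- w[!dup]
    }
  }
  values <- matrix(0, nrow = length(source), ncol = length(target))
  values[cbind(ri, ci)] <- w
  as_relation(values, source, target)
}

#' Load a relation matrix from a TSV edge list
#'
#' @inheritParams read_edges
#' @inheritParams relation_from_edges
#' @return A relation matrix; see [relation_from_edges()].
#' @export
load_relation <- function(path, source, target) {
  relation_from_edges(read_edges(path), source, target)
}

#' Write the nonzero entries of a relation matrix as a TSV edge list
#'
#' @param relation A relation matrix (rows and columns named by catalog ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relation <- function(relation, path) {
  nz <- which(relation != 0, arr.ind = TRUE)
  edges <- tibble(
    source_id = rownames(relation)[nz[, 1L]],
    target_id = colnames(relation)[nz[, 2L]],
    weight = relation[nz]
  )
  edges <- dplyr::arrange(edges, .data$source_id, .data$target_id)
  readr::write_tsv(edges, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Binarize a prognosis-score matrix
#'
#' Gene-prognosis relations arrive as real scores in `[0, 1]`; a gene is
#' called prognosis-associated when its score is strictly greater than the
#' threshold (score 0.5 maps to 0 at the default threshold of 0.5).
#'
#' @param scores Numeric matrix with entries in `[0, 1]`.
#' @param threshold Strict cutoff; entries become 1 iff `> threshold`.
#' @return A binary matrix of the same shape, attributes preserved.
#' @export
binarize_prognosis <- function(scores, threshold = 0.5) {
  if (!all(is.finite(scores))) {
    abort("prognosis scores contain non-finite values.")
  }
  if (any(scores < 0 | scores > 1)) {
    abort("prognosis scores must lie in [0, 1].")
  }
  out <- (scores > threshold) * 1
  dimnames(out) <- dimnames(scores)
  attr(out, "source_type") <- attr(scores, "source_type")
  attr(out, "target_type") <- attr(scores, "target_type")
  out
}
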
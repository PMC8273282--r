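#' Create an entity catalog
#'
#' An entity catalog is the ordered list of identifiers for one entity type
#' (e.g. `"lncRNA"`, `"miRNA"`, `"gene"`, `"cancer"`, `"prognosis"`). The
#' position of an identifier in the catalog defines its row/column in every
#' relation matrix indexed by that type, so the order is part of the data
#' contract: reloading the same file yields the same index for every id.
#'
#' @param ids Character vector of unique, non-empty identifiers, in order.
#' @param entity_type Single string naming the entity type. Must not contain
#'   `"~"`, which separates the two types in a relation key.
#' @return An `entity_catalog`: a character vector with an `entity_type`
#'   attribute.
#' @examples
#' entity_catalog(c("L1", "L2", "L3"), "lncRNA")
#' @export
entity_catalog <- function(ids, entity_type) {
  if (!is.character(entity_type) || length(entity_type) != 1L || !nzchar(entity_type)) {
    abort("`entity_type` must be a single non-empty string.")
  }
  if (grepl("~", entity_type, fixed = TRUE)) {
    abort("`entity_type` must not contain '~' (reserved as the relation-key separator).")
  }
  ids <- as.character(ids)
  if (length(ids) == 0L) {
    abort(sprintf("catalog for entity type '%s' is empty.", entity_type))
  }
  if (anyNA(ids) || !all(nzchar(ids))) {
    abort(sprintf("catalog for '%s' contains missing or empty identifiers.", entity_type))
  }
  dup <- which(duplicated(ids))
  if (length(dup) > 0L) {
    abort(sprintf(
      "duplicate identifier '%s' at position %d in '%s' catalog.",
      ids[dup[1L]], dup[1L], entity_type
    ))
  }
  structure(ids, entity_type = entity_type, class = "entity_catalog")
}

#' Read an entity catalog from a plain-text file
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored. Duplicated identifiers are rejected with the offending line
#' number.
#'
#' @param path Path to the file.
#' @inheritParams entity_catalog
#' @return An [entity_catalog()].
#' @export
read_catalog <- function(path, entity_type) {
  if (!file.exists(path)) {
    abort(sprintf("catalog file '%s' does not exist.", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  ids <- trimws(lines[keep])
  if (length(ids) == 0L) {
    abort(sprintf("catalog file '%s' contains no identifiers.", path))
  }
  dup <- which(duplicated(ids))
  if (length(dup) > 0L) {
    abort(sprintf(
      "duplicate identifier '%s' at line %d of '%s'.",
      ids[dup[1L]], keep[dup[1L]], path
    ))
  }
  entity_catalog(ids, entity_type)
}

#' Write an entity catalog to a plain-text file
#'
#' @param catalog An [entity_catalog()].
#' @param path Output path, one identifier per line.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "entity_catalog"))
  writeLines(as.character(catalog), path)
  invisible(path)
}

#' @export
print.entity_catalog <- function(x, ...) {
  cat(sprintf(
    "<entity_catalog> %s: %d identifiers (%s%s)\n",
    attr(x, "entity_type"), length(x),
    paste(utils::head(unclass(x), 3L), collapse = ", "),
    if (length(x) > 3L) ", ..." else ""
  ))
  invisible(x)
}

catalog_type <- function(catalog) attr(catalog, "entity_type")

# Resolve identifiers to 1-based positions, failing loudly on unknown ids.
catalog_match <- function(catalog, ids, context = "identifier") {
  idx <- match(ids, catalog)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    abort(sprintf(
      "unknown %s '%s' (not in '%s' catalog).",
      context, ids[bad], catalog_type(catalog)
    ))
  }
  idx
}
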
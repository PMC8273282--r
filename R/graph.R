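#' Assemble a multi-type relation graph
#'
#' A relation graph bundles the entity catalogs with the observed relation
#' blocks between them. One block — the target (lncRNA~cancer in the
#' motivating application) — is the one whose unobserved cells are scored;
#' the remaining blocks are the side information fused into the prediction.
#'
#' @param catalogs List of [entity_catalog()]s (names taken from their
#'   `entity_type` attributes).
#' @param relations Named list of relation matrices; each name is a
#'   `"source~target"` key (see [relation_key()]). Each unordered type pair
#'   may appear at most once and matrix dimensions must match the catalogs.
#' @param target_key Key of the block to predict; must be present in
#'   `relations`.
#' @param aligned Optional named character vector declaring that one catalog
#'   is positionally aligned with another (e.g. `c(prognosis = "cancer")`:
#'   prognosis column `j` refers to cancer `j`). When both a `"prognosis"`
#'   catalog and the target's column catalog exist with equal lengths the
#'   alignment is inferred automatically. Aligned catalogs are sliced
#'   together by [restrict_to_cancer()].
#' @return A `relation_graph` object.
#' @export
relation_graph <- function(catalogs, relations, target_key, aligned = NULL) {
  if (length(catalogs) == 0L) abort("`catalogs` is empty.")
  types <- vapply(catalogs, catalog_type, character(1L))
  if (anyDuplicated(types)) {
    abort(sprintf("duplicate catalog for entity type '%s'.", types[duplicated(types)][1L]))
  }
  names(catalogs) <- types

  if (length(relations) == 0L) abort("`relations` is empty.")
  keys <- names(relations)
  if (is.null(keys) || any(!nzchar(keys))) {
    abort("`relations` must be a named list with 'source~target' keys.")
  }
  unordered <- vapply(
    keys,
    function(k) paste(sort(split_relation_key(k)), collapse = "~"),
    character(1L)
  )
  if (anyDuplicated(unordered)) {
    abort(sprintf(
      "duplicate relation for type pair '%s'.",
      unordered[duplicated(unordered)][1L]
    ))
  }
  relations <- lapply(keys, function(k) {
    pair <- split_relation_key(k)
    for (ty in pair) {
      if (!ty %in% types) {
        abort(sprintf("relation '%s' references undeclared entity type '%s'.", k, ty))
      }
    }
    as_relation(relations[[k]], catalogs[[pair[1L]]], catalogs[[pair[2L]]])
  })
  names(relations) <- keys

  if (length(target_key) != 1L || !target_key %in% keys) {
    abort(sprintf("target_key '%s' is not among the declared relations.", target_key[1L]))
  }

  target_col_type <- split_relation_key(target_key)[2L]
  if (is.null(aligned) &&
      "prognosis" %in% types && target_col_type != "prognosis" &&
      length(catalogs[["prognosis"]]) == length(catalogs[[target_col_type]])) {
    aligned <- c(prognosis = target_col_type)
  }
  if (!is.null(aligned)) {
    for (i in seq_along(aligned)) {
      a <- names(aligned)[i]
      b <- aligned[[i]]
      if (!a %in% types || !b %in% types) {
        abort(sprintf("aligned pair '%s'='%s' references unknown entity types.", a, b))
      }
      if (length(catalogs[[a]]) != length(catalogs[[b]])) {
        abort(sprintf(
          "aligned catalogs '%s' (%d) and '%s' (%d) differ in length.",
          a, length(catalogs[[a]]), b, length(catalogs[[b]])
        ))
      }
    }
  }

  structure(
    list(
      catalogs = catalogs,
      relations = relations,
      target_key = target_key,
      aligned = aligned
    ),
    class = "relation_graph"
  )
}

#' @export
print.relation_graph <- function(x, ...) {
  cat(sprintf(
    "<relation_graph> %d entity types, %d relation blocks (target: %s)\n",
    length(x$catalogs), length(x$relations), x$target_key
  ))
  for (key in names(x$relations)) {
    rel <- x$relations[[key]]
    cat(sprintf(
      "  %-22s %6d x %-6d %8d nonzero%s\n",
      key, nrow(rel), ncol(rel), sum(rel != 0),
      if (key == x$target_key) "  [target]" else ""
    ))
  }
  invisible(x)
}

graph_types <- function(graph) names(graph$catalogs)

#' Extract the target relation matrix
#'
#' @param graph A [relation_graph()].
#' @return The matrix of the target block.
#' @export
target_matrix <- function(graph) {
  graph$relations[[graph$target_key]]
}

#' Restrict a graph to a single cancer
#'
#' Keeps only `cancer_id` in the cancer catalog (the target's column type)
#' and the matching position of every catalog aligned with it (the
#' prognosis columns are keyed to cancers). Blocks indexed by the sliced
#' catalogs keep only that row/column; all other blocks are unchanged. The
#' operation is idempotent.
#'
#' @param graph A [relation_graph()].
#' @param cancer_id Identifier present in the cancer catalog.
#' @return A new, validated [relation_graph()].
#' @export
restrict_to_cancer <- function(graph, cancer_id) {
  stopifnot(inherits(graph, "relation_graph"))
  ctype <- split_relation_key(graph$target_key)[2L]
  idx <- catalog_match(graph$catalogs[[ctype]], cancer_id, context = "cancer identifier")
  slice_types <- c(ctype, names(graph$aligned)[graph$aligned == ctype])

  catalogs <- graph$catalogs
  for (ty in slice_types) {
    catalogs[[ty]] <- entity_catalog(as.character(catalogs[[ty]])[idx], ty)
  }
  relations <- lapply(names(graph$relations), function(key) {
    pair <- split_relation_key(key)
    rel <- graph$relations[[key]]
    if (pair[1L] %in% slice_types) rel <- rel[idx, , drop = FALSE]
    if (pair[2L] %in% slice_types) rel <- rel[, idx, drop = FALSE]
    rel
  })
  names(relations) <- names(graph$relations)
  relation_graph(catalogs, relations, graph$target_key, aligned = graph$aligned)
}

#' Drop a relation block from a graph
#'
#' Removes one non-target block (the ablation primitive). Entity types left
#' without any incident block are pruned from the catalogs, except the two
#' types of the target.
#'
#' @param graph A [relation_graph()].
#' @param key Relation key to remove; dropping the target is an error.
#' @return A new [relation_graph()].
#' @export
drop_relation <- function(graph, key) {
  stopifnot(inherits(graph, "relation_graph"))
  if (!key %in% names(graph$relations)) {
    abort(sprintf("relation '%s' is not in the graph.", key))
  }
  if (key == graph$target_key) {
    abort("the target relation cannot be dropped.")
  }
  relations <- graph$relations[setdiff(names(graph$relations), key)]
  used <- unique(c(
    unlist(lapply(names(relations), split_relation_key)),
    split_relation_key(graph$target_key)
  ))
  catalogs <- graph$catalogs[intersect(graph_types(graph), used)]
  aligned <- graph$aligned
  if (!is.null(aligned)) {
    keep <- names(aligned) %in% used & aligned %in% used
    aligned <- if (any(keep)) aligned[keep] else NULL
  }
  relation_graph(catalogs, relations, graph$target_key, aligned = aligned)
}

#' Summarize a relation graph
#'
#' One row per block: shape and nonzero count; for the target block also the
#' positive count and the negative count (cells with value 0 — unobserved
#' pairs are treated as negatives, no missing-value mask).
#'
#' @param graph A [relation_graph()].
#' @return A tibble with columns `relation`, `source_type`, `target_type`,
#'   `n_source`, `n_target`, `nonzero`, `positives`, `negatives`.
#' @export
dataset_summary <- function(graph) {
  stopifnot(inherits(graph, "relation_graph"))
  purrr::map_dfr(names(graph$relations), function(key) {
    rel <- graph$relations[[key]]
    pair <- split_relation_key(key)
    is_target <- key == graph$target_key
    nnz <- sum(rel != 0)
    tibble(
      relation = key,
      source_type = pair[1L],
      target_type = pair[2L],
      n_source = nrow(rel),
      n_target = ncol(rel),
      nonzero = nnz,
      positives = if (is_target) nnz else NA_integer_,
      negatives = if (is_target) nrow(rel) * ncol(rel) - nnz else NA_integer_
    )
  })
}
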
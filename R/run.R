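#' Read a run configuration from YAML or JSON
#'
#' A single configuration file drives every run command. Recognized fields:
#'
#' * `seed`, `outdir`
#' * `target`: two-element vector `(source_type, target_type)`
#' * `catalogs`: named map entity type -> catalog file path
#' * `relations`: list of records with `source`, `target`, `path`, and
#'   optional `binarize` (threshold for real-valued scores, e.g. 0.5 for
#'   gene-prognosis blocks)
#' * `ranks`: named map entity type -> low-rank size
#' * `fit`: `alpha`, `max_iter`, `tol`
#' * `cv`: `k`
#' * `rank_search`: `axes`, `grids`
#' * `ablate`: `keys` (optional; defaults to all non-target blocks)
#' * `synthetic`: arguments for [synthetic_config()]; used instead of
#'   `catalogs`/`relations` when present
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The configuration as a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist.", path))
  ext <- tolower(tools::file_ext(path))
  config <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(sprintf("unsupported config extension '.%s' (use YAML or JSON).", ext))
  )
  config
}

config_seed <- function(config) as.integer(config$seed %||% 1L)

# Output location is provenance-irrelevant: two runs of the same analysis
# into different directories hash identically.
config_hash <- function(config) rlang::hash(config[setdiff(names(config), "outdir")])

config_fit_args <- function(config) {
  fit <- config$fit %||% list()
  list(
    alpha = as.numeric(fit$alpha %||% 1e5),
    max_iter = as.integer(fit$max_iter %||% 200L),
    tol = as.numeric(fit$tol %||% 1e-6)
  )
}

config_ranks <- function(config, graph) {
  if (is.null(config$ranks)) {
    abort("config is missing `ranks` (named map entity type -> k).")
  }
  unlist(config$ranks)[graph_types(graph)]
}

config_synthetic <- function(config) {
  syn <- config$synthetic %||% list()
  args <- list()
  for (field in c("n", "ranks", "density", "membership_prob")) {
    if (!is.null(syn[[field]])) args[[field]] <- unlist(syn[[field]])
  }
  for (field in c("noise", "informative_key", "holdout", "target_key")) {
    if (!is.null(syn[[field]])) args[[field]] <- syn[[field]]
  }
  args$seed <- as.integer(syn$seed %||% config_seed(config))
  do.call(synthetic_config, args)
}

#' Build the input graph described by a run configuration
#'
#' Reads catalogs and edge lists from the configured paths (binarizing
#' real-valued blocks where requested), or generates a synthetic graph when
#' the config has a `synthetic` section and no file inputs.
#'
#' @param config A configuration list from [read_run_config()].
#' @return A [relation_graph()].
#' @export
config_graph <- function(config) {
  if (is.null(config$catalogs)) {
    if (is.null(config$synthetic)) {
      abort("config needs either `catalogs` + `relations` or a `synthetic` section.")
    }
    return(generate_synthetic(config_synthetic(config))$graph)
  }
  catalogs <- lapply(names(config$catalogs), function(ty) {
    read_catalog(config$catalogs[[ty]], ty)
  })
  names(catalogs) <- names(config$catalogs)
  if (is.null(config$relations) || is.null(config$target)) {
    abort("config with `catalogs` also needs `relations` and `target`.")
  }
  relations <- list()
  for (rec in config$relations) {
    key <- relation_key(rec$source, rec$target)
    rel <- load_relation(rec$path, catalogs[[rec$source]], catalogs[[rec$target]])
    if (!is.null(rec$binarize)) {
      rel <- binarize_prognosis(rel, threshold = as.numeric(rec$binarize))
    }
    relations[[key]] <- rel
  }
  target_key <- relation_key(config$target[[1L]], config$target[[2L]])
  relation_graph(catalogs, relations, target_key)
}

# Write a TSV report with a provenance header (seed + config hash), so
# repeated runs with the same config are byte-identical.
write_report <- function(df, path, config) {
  header <- c(
    sprintf("# seed: %d", config_seed(config)),
    sprintf("# config_hash: %s", config_hash(config))
  )
  body <- sub("\n$", "", readr::format_tsv(df))
  writeLines(c(header, body), path)
  invisible(path)
}

ensure_outdir <- function(config, outdir = NULL) {
  outdir <- outdir %||% config$outdir %||% "trifuse_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outdir
}

write_matrix_tsv <- function(mat, path) {
  df <- as.data.frame(mat)
  names(df) <- sprintf("c%d", seq_len(ncol(mat)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Fit a model from a run configuration
#'
#' Fits the fusion model and writes the model archive (factor and core
#' matrices, weight table, objective trace, configuration echo) plus the
#' full target score table.
#'
#' @param config A configuration list (or path to one).
#' @param outdir Output directory; defaults to `config$outdir`.
#' @return The `trifuse_fit`, invisibly.
#' @export
run_fit <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- ensure_outdir(config, outdir)
  graph <- config_graph(config)
  args <- config_fit_args(config)
  fit <- fit_trifuse(
    graph, config_ranks(config, graph),
    alpha = args$alpha, max_iter = args$max_iter, tol = args$tol,
    seed = config_seed(config)
  )
  write_report(tidy(fit), file.path(outdir, "weights.tsv"), config)
  write_report(
    tibble(sweep = seq_along(fit$objective_trace) - 1L, objective = fit$objective_trace),
    file.path(outdir, "objective_trace.tsv"), config
  )
  write_report(score_target(fit), file.path(outdir, "scores.tsv"), config)
  model_dir <- file.path(outdir, "model")
  dir.create(model_dir, showWarnings = FALSE)
  for (ty in names(fit$factors$G)) {
    write_matrix_tsv(fit$factors$G[[ty]], file.path(model_dir, sprintf("G_%s.tsv", ty)))
  }
  for (key in names(fit$factors$S)) {
    write_matrix_tsv(
      fit$factors$S[[key]],
      file.path(model_dir, sprintf("S_%s.tsv", gsub("~", "_", key, fixed = TRUE)))
    )
  }
  jsonlite::write_json(
    list(seed = config_seed(config), config_hash = config_hash(config),
         ranks = as.list(fit$ranks), alpha = fit$alpha, tol = fit$tol,
         n_iter = fit$n_iter, converged = fit$converged),
    file.path(model_dir, "config.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(fit)
}

#' Cross-validate from a run configuration
#'
#' @inheritParams run_fit
#' @return The `trifuse_cv`, invisibly.
#' @export
run_cv <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- ensure_outdir(config, outdir)
  graph <- config_graph(config)
  args <- config_fit_args(config)
  cv <- cross_validate(
    graph, config_ranks(config, graph),
    alpha = args$alpha, max_iter = args$max_iter, tol = args$tol,
    k = as.integer((config$cv %||% list())$k %||% 10L),
    seed = config_seed(config)
  )
  write_report(tidy(cv), file.path(outdir, "cv_folds.tsv"), config)
  write_report(glance(cv), file.path(outdir, "cv_summary.tsv"), config)
  invisible(cv)
}

#' Coordinate rank search from a run configuration
#'
#' Grids default to the published pattern (start 10, step 100, capped at the
#' axis size) when not given explicitly.
#'
#' @inheritParams run_fit
#' @return The `trifuse_rank_search`, invisibly.
#' @export
run_rank_search <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- ensure_outdir(config, outdir)
  graph <- config_graph(config)
  args <- config_fit_args(config)
  rs_conf <- config$rank_search %||% list()
  axes <- unlist(rs_conf$axes %||% c("miRNA", "gene"))
  grids <- lapply(rs_conf$grids %||% stats::setNames(vector("list", length(axes)), axes),
                  unlist)
  for (axis in axes) {
    if (is.null(grids[[axis]])) {
      grids[[axis]] <- default_rank_grid(length(graph$catalogs[[axis]]))
    }
  }
  rs <- rank_search(
    graph, axes = axes, grids = grids, ranks = config_ranks(config, graph),
    alpha = args$alpha, max_iter = args$max_iter, tol = args$tol,
    k = as.integer((config$cv %||% list())$k %||% 10L),
    seed = config_seed(config)
  )
  write_report(tidy(rs), file.path(outdir, "rank_search.tsv"), config)
  invisible(rs)
}

#' Relation ablation from a run configuration
#'
#' @inheritParams run_fit
#' @return The ablation tibble, invisibly.
#' @export
run_ablate <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- ensure_outdir(config, outdir)
  graph <- config_graph(config)
  args <- config_fit_args(config)
  tab <- ablate(
    graph,
    keys = unlist((config$ablate %||% list())$keys),
    ranks = config_ranks(config, graph),
    alpha = args$alpha, max_iter = args$max_iter, tol = args$tol,
    k = as.integer((config$cv %||% list())$k %||% 10L),
    seed = config_seed(config)
  )
  write_report(tab, file.path(outdir, "ablation.tsv"), config)
  invisible(tab)
}

#' Generate and export a synthetic dataset from a run configuration
#'
#' Writes the catalogs and edge lists the relation module reads back, plus
#' the held-out truth list.
#'
#' @inheritParams run_fit
#' @return The `trifuse_sim`, invisibly.
#' @export
run_simulate <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- ensure_outdir(config, outdir)
  sim <- generate_synthetic(config_synthetic(config))
  for (ty in graph_types(sim$graph)) {
    write_catalog(sim$graph$catalogs[[ty]], file.path(outdir, sprintf("catalog_%s.txt", ty)))
  }
  for (key in names(sim$graph$relations)) {
    write_relation(
      sim$graph$relations[[key]],
      file.path(outdir, sprintf("edges_%s.tsv", gsub("~", "_", key, fixed = TRUE)))
    )
  }
  write_report(sim$truth, file.path(outdir, "truth.tsv"), config)
  invisible(sim)
}
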
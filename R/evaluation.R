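#' Rank-based AUC with midrank tie handling
#'
#' Equals the probability that a random positive outscores a random negative
#' plus half the probability of a tie (the Mann-Whitney statistic divided by
#' `n_pos * n_neg`).
#'
#' @param scores Numeric vector of prediction scores.
#' @param labels 0/1 vector of the same length; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  check_scores_labels(scores, labels, require_both = TRUE)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_scores_labels <- function(scores, labels, require_both = FALSE) {
  if (length(scores) == 0L) abort("`scores` is empty.")
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have the same length.")
  }
  if (anyNA(scores) || anyNA(labels)) abort("scores/labels contain missing values.")
  if (!all(labels %in% c(0, 1))) abort("`labels` must be 0/1.")
  if (require_both && (all(labels == 0) || all(labels == 1))) {
    abort("both classes must be present in `labels`.")
  }
  invisible(TRUE)
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' A pair is predicted positive iff its score is strictly greater than the
#' threshold. MCC is defined as 0 when any factor of its denominator is 0;
#' precision (sensitivity, specificity) is defined as 0 when its denominator
#' is 0.
#'
#' @inheritParams auc_score
#' @param threshold Finite score cutoff.
#' @return A one-row tibble: `threshold`, `tp`, `fp`, `fn`, `tn`, `mcc`,
#'   `acc`, `precision`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  check_scores_labels(scores, labels)
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  pred <- scores > threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  tibble(
    threshold = threshold,
    tp = tp, fp = fp, fn = fn, tn = tn,
    mcc = mcc,
    acc = (tp + tn) / length(scores),
    precision = safe_div(tp, tp + fp),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, fp + tn)
  )
}

#' Threshold maximizing the Matthews correlation coefficient
#'
#' Scans candidate thresholds at the midpoints between consecutive distinct
#' sorted scores, plus a below-minimum sentinel (predict everything
#' positive) and an above-maximum sentinel (predict everything negative).
#' Ties are broken toward the lowest threshold.
#'
#' @inheritParams auc_score
#' @return A list with `threshold` and `metrics` (the [confusion_metrics()]
#'   row at that threshold).
#' @export
best_mcc_threshold <- function(scores, labels) {
  check_scores_labels(scores, labels, require_both = TRUE)
  ss <- sort(unique(scores))
  cand <- c(
    ss[1L] - 1,
    if (length(ss) > 1L) (ss[-length(ss)] + ss[-1L]) / 2,
    ss[length(ss)] + 1
  )
  mccs <- vapply(cand, function(th) confusion_metrics(scores, labels, th)$mcc, numeric(1L))
  best <- cand[which.max(mccs)] # first max = lowest threshold (cand ascending)
  list(threshold = best, metrics = confusion_metrics(scores, labels, best))
}

#' Stratified fold assignment over target cells
#'
#' Every cell of the target block (an lncRNA-cancer pair) is assigned to one
#' of `k` folds; the assignment is stratified by label so positive and
#' negative fold sizes each differ by at most 1. Deterministic given `seed`.
#'
#' @param graph A [relation_graph()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return A tibble with one row per target cell: `row`, `col` (1-based
#'   indices), the two identifier columns, `label` and `fold`.
#' @export
make_folds <- function(graph, k = 10L, seed = 1L) {
  stopifnot(inherits(graph, "relation_graph"))
  if (k < 2L) abort("`k` must be >= 2.")
  tm <- target_matrix(graph)
  pair <- split_relation_key(graph$target_key)
  cells <- tibble(
    row = rep(seq_len(nrow(tm)), times = ncol(tm)),
    col = rep(seq_len(ncol(tm)), each = nrow(tm)),
    !!pair[1L] := rep(rownames(tm), times = ncol(tm)),
    !!pair[2L] := rep(colnames(tm), each = nrow(tm)),
    label = as.vector((tm != 0) * 1)
  )
  counts <- table(factor(cells$label, levels = c(0, 1)))
  if (any(counts < k)) {
    abort(sprintf(
      "a label class has only %d cells, fewer than k = %d folds; use a smaller k.",
      min(counts), k
    ))
  }
  cells$fold <- NA_integer_
  withr::with_seed(seed, {
    for (lab in c(1, 0)) {
      idx <- which(cells$label == lab)
      cells$fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  attr(cells, "k") <- as.integer(k)
  attr(cells, "seed") <- as.integer(seed)
  cells
}

#' Mask the test positives of one fold
#'
#' Zeroes the target cells that are positive and belong to the given fold,
#' producing the training graph for that fold. Negatives are already 0 and
#' need no masking.
#'
#' @param graph A [relation_graph()].
#' @param folds A fold table from [make_folds()].
#' @param fold Fold id to hold out.
#' @return The masked [relation_graph()].
#' @export
mask_test_positives <- function(graph, folds, fold) {
  tm <- target_matrix(graph)
  test_pos <- folds[folds$fold == fold & folds$label == 1, , drop = FALSE]
  tm[cbind(test_pos$row, test_pos$col)] <- 0
  relations <- graph$relations
  relations[[graph$target_key]] <- tm
  relation_graph(graph$catalogs, relations, graph$target_key, aligned = graph$aligned)
}

#' Masked k-fold cross-validation of target scoring
#'
#' For each fold the fold's positive target cells are zeroed, the model is
#' fitted on the masked graph, and the fold's cells (positives and
#' negatives) are scored from the reconstructed target block. Reports
#' per-fold AUC and confusion metrics at the fold's own best-MCC threshold,
#' the mean of fold AUCs (the headline statistic), and the best-MCC metric
#' set over the pooled out-of-fold scores (the default threshold used to
#' call candidate associations).
#'
#' @inheritParams fit_trifuse
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param folds Optional precomputed fold table (from [make_folds()]);
#'   overrides `k`/`seed` for the assignment.
#' @return A `trifuse_cv` object.
#' @export
cross_validate <- function(graph, ranks, alpha = 1e5, max_iter = 200L, tol = 1e-6,
                           k = 10L, seed = 1L, epsilon = 1e-12, folds = NULL) {
  stopifnot(inherits(graph, "relation_graph"))
  folds <- folds %||% make_folds(graph, k = k, seed = seed)
  k <- attr(folds, "k") %||% max(folds$fold)
  oof <- rep(NA_real_, nrow(folds))
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    g_train <- mask_test_positives(graph, folds, f)
    fit <- tryCatch(
      fit_trifuse(g_train, ranks, alpha = alpha, max_iter = max_iter,
                  tol = tol, seed = seed, epsilon = epsilon),
      error = function(e) abort(sprintf("fit failed in fold %d: %s", f, conditionMessage(e)))
    )
    scores <- reconstruct(fit)
    in_fold <- folds$fold == f
    sc <- scores[cbind(folds$row[in_fold], folds$col[in_fold])]
    oof[in_fold] <- sc
    lab <- folds$label[in_fold]
    best <- best_mcc_threshold(sc, lab)
    fold_metrics[[f]] <- dplyr::bind_cols(
      tibble(fold = f, auc = auc_score(sc, lab)),
      best$metrics
    )
  }
  metrics <- dplyr::bind_rows(fold_metrics)
  pooled <- best_mcc_threshold(oof, folds$label)
  folds$score <- oof
  structure(
    list(
      metrics = metrics,
      mean_auc = mean(metrics$auc),
      pooled = pooled,
      folds = folds,
      ranks = ranks,
      alpha = alpha,
      k = k,
      seed = seed
    ),
    class = "trifuse_cv"
  )
}

#' @export
print.trifuse_cv <- function(x, ...) {
  cat(sprintf(
    "<trifuse_cv> %d folds: mean AUC %.3f (sd %.3f), pooled best MCC %.3f at threshold %.4g\n",
    x$k, x$mean_auc, stats::sd(x$metrics$auc),
    x$pooled$metrics$mcc, x$pooled$threshold
  ))
  invisible(x)
}

#' @describeIn cross_validate Per-fold metric table.
#' @param x A `trifuse_cv`.
#' @param ... Unused.
#' @method tidy trifuse_cv
#' @export
tidy.trifuse_cv <- function(x, ...) {
  x$metrics
}

#' @describeIn cross_validate One-row cross-validation summary.
#' @method glance trifuse_cv
#' @export
glance.trifuse_cv <- function(x, ...) {
  tibble(
    mean_auc = x$mean_auc,
    sd_auc = stats::sd(x$metrics$auc),
    pooled_threshold = x$pooled$threshold,
    pooled_mcc = x$pooled$metrics$mcc,
    pooled_acc = x$pooled$metrics$acc,
    pooled_precision = x$pooled$metrics$precision,
    pooled_sensitivity = x$pooled$metrics$sensitivity,
    pooled_specificity = x$pooled$metrics$specificity,
    k = x$k,
    seed = x$seed
  )
}

# ROC points of a score/label vector (for plotting).
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tibble(
    fpr = c(0, cumsum(lab == 0) / sum(lab == 0)),
    tpr = c(0, cumsum(lab == 1) / sum(lab == 1))
  )
}

#' @describeIn cross_validate ROC curve of the pooled out-of-fold scores.
#' @param object A `trifuse_cv`.
#' @method autoplot trifuse_cv
#' @export
autoplot.trifuse_cv <- function(object, ...) {
  df <- roc_points(object$folds$score, object$folds$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("Pooled out-of-fold ROC (mean fold AUC %.3f)", object$mean_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Default low-rank search grid
#'
#' Mirrors the published search pattern: from 10 up to the axis size in
#' steps of 100 (e.g. an axis of size 2,759 yields 10, 110, ..., 2,710).
#'
#' @param n_max Axis size (upper bound of the grid).
#' @param from,step Grid start and step.
#' @return Integer vector of candidate ranks.
#' @export
default_rank_grid <- function(n_max, from = 10L, step = 100L) {
  if (n_max < from) return(as.integer(n_max))
  as.integer(seq.int(from, n_max, by = step))
}

#' Coordinate search over low-rank sizes
#'
#' Optimizes one axis at a time: the first axis is swept over its grid with
#' all other ranks held at `ranks`, the best value (ties toward the smaller
#' k) is fixed, and the next axis is swept. The selection criterion is the
#' cross-validated mean AUC at a fixed seed.
#'
#' @inheritParams cross_validate
#' @param axes Character vector of entity types to search, in order.
#' @param grids Named list of integer grids, one per searched axis.
#' @param ranks Baseline named rank vector (holds the non-searched axes and
#'   the not-yet-searched axes, e.g. the second axis at 50).
#' @return A `trifuse_rank_search` object with the selected `ranks` and the
#'   full AUC-vs-k `table`.
#' @export
rank_search <- function(graph, axes, grids, ranks, alpha = 1e5, max_iter = 200L,
                        tol = 1e-6, k = 10L, seed = 1L, epsilon = 1e-12) {
  stopifnot(inherits(graph, "relation_graph"))
  if (!all(axes %in% names(grids))) {
    abort("every searched axis needs a grid in `grids`.")
  }
  current <- stats::setNames(as.integer(unlist(ranks)), names(ranks))
  rows <- list()
  for (axis in axes) {
    grid <- sort(unique(as.integer(grids[[axis]])))
    if (length(grid) == 0L) abort(sprintf("empty grid for axis '%s'.", axis))
    aucs <- vapply(grid, function(kk) {
      trial <- current
      trial[[axis]] <- kk
      cv <- suppressWarnings(cross_validate(
        graph, trial, alpha = alpha, max_iter = max_iter, tol = tol,
        k = k, seed = seed, epsilon = epsilon
      ))
      cv$mean_auc
    }, numeric(1L))
    best_k <- grid[which.max(aucs)] # grid ascending: first max = smallest k
    rows[[axis]] <- tibble(
      axis = axis, k = grid, mean_auc = aucs, selected = grid == best_k
    )
    current[[axis]] <- best_k
  }
  structure(
    list(ranks = current, table = dplyr::bind_rows(rows), axes = axes, seed = seed),
    class = "trifuse_rank_search"
  )
}

#' @export
print.trifuse_rank_search <- function(x, ...) {
  sel <- dplyr::filter(x$table, .data$selected)
  cat("<trifuse_rank_search>\n")
  for (i in seq_len(nrow(sel))) {
    cat(sprintf("  %s: k = %d (mean AUC %.3f)\n", sel$axis[i], sel$k[i], sel$mean_auc[i]))
  }
  invisible(x)
}

#' @describeIn rank_search The AUC-vs-k table.
#' @param x A `trifuse_rank_search`.
#' @param ... Unused.
#' @method tidy trifuse_rank_search
#' @export
tidy.trifuse_rank_search <- function(x, ...) {
  x$table
}

#' @describeIn rank_search AUC against k, one panel per searched axis.
#' @param object A `trifuse_rank_search`.
#' @method autoplot trifuse_rank_search
#' @export
autoplot.trifuse_rank_search <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$k, y = .data$mean_auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected)) +
    ggplot2::facet_wrap(~axis, scales = "free_x") +
    ggplot2::labs(x = "low-rank size k", y = "mean CV AUC") +
    ggplot2::theme_minimal()
}

#' Relation ablation experiment
#'
#' Re-runs cross-validation after removing each listed relation block in
#' turn (identical folds throughout) and reports the change in mean AUC and
#' pooled best MCC against the baseline with all blocks present.
#'
#' @inheritParams cross_validate
#' @param keys Relation keys to drop one at a time; defaults to every
#'   non-target block. Dropping the target is an error.
#' @return A tibble with one row for the baseline (`dropped = "none"`) and
#'   one per dropped block: `mean_auc`, `best_mcc`, `delta_auc`, `delta_mcc`.
#' @export
ablate <- function(graph, keys = NULL, ranks, alpha = 1e5, max_iter = 200L,
                   tol = 1e-6, k = 10L, seed = 1L, epsilon = 1e-12) {
  stopifnot(inherits(graph, "relation_graph"))
  keys <- keys %||% setdiff(names(graph$relations), graph$target_key)
  if (graph$target_key %in% keys) {
    abort("the target relation cannot be ablated.")
  }
  if (!all(keys %in% names(graph$relations))) {
    abort(sprintf(
      "unknown relation key(s): %s.",
      paste(setdiff(keys, names(graph$relations)), collapse = ", ")
    ))
  }
  folds <- make_folds(graph, k = k, seed = seed)
  run_cv <- function(g) {
    suppressWarnings(cross_validate(
      g, ranks, alpha = alpha, max_iter = max_iter, tol = tol,
      seed = seed, epsilon = epsilon, folds = folds
    ))
  }
  baseline <- run_cv(graph)
  rows <- list(tibble(
    dropped = "none",
    mean_auc = baseline$mean_auc,
    best_mcc = baseline$pooled$metrics$mcc,
    delta_auc = 0,
    delta_mcc = 0
  ))
  for (key in keys) {
    cv <- run_cv(drop_relation(graph, key))
    rows[[key]] <- tibble(
      dropped = key,
      mean_auc = cv$mean_auc,
      best_mcc = cv$pooled$metrics$mcc,
      delta_auc = cv$mean_auc - baseline$mean_auc,
      delta_mcc = cv$pooled$metrics$mcc - baseline$pooled$metrics$mcc
    )
  }
  dplyr::bind_rows(rows)
}
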
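#' Squared Frobenius reconstruction residual of one block
#'
#' `H_ij = || R_ij - G_i S_ij G_j' ||_F^2`, the quantity that drives both the
#' factor updates and the relation-weight update.
#'
#' @param R Observed relation matrix (`n_i x n_j`).
#' @param Gi,Gj Factor matrices (`n_i x k_i`, `n_j x k_j`).
#' @param S Core matrix (`k_i x k_j`).
#' @return A single non-negative number.
#' @export
reconstruction_residual <- function(R, Gi, S, Gj) {
  if (nrow(R) != nrow(Gi) || ncol(R) != nrow(Gj) ||
      ncol(Gi) != nrow(S) || ncol(S) != ncol(Gj)) {
    abort(sprintf(
      "non-conformable shapes: R %dx%d, Gi %dx%d, S %dx%d, Gj %dx%d.",
      nrow(R), ncol(R), nrow(Gi), ncol(Gi), nrow(S), ncol(S), nrow(Gj), ncol(Gj)
    ))
  }
  sum((R - Gi %*% S %*% t(Gj))^2)
}

# Squared Frobenius residual of every block under the current factors.
block_residuals <- function(graph, factors) {
  keys <- names(graph$relations)
  vapply(keys, function(key) {
    pair <- split_relation_key(key)
    reconstruction_residual(
      graph$relations[[key]],
      factors$G[[pair[1L]]], factors$S[[key]], factors$G[[pair[2L]]]
    )
  }, numeric(1L))
}

#' Weighted fusion objective
#'
#' `sum_ij w_ij H_ij + alpha * sum_ij w_ij^2`, where `H_ij` is the squared
#' Frobenius residual of block `ij` and the quadratic penalty (weighted by
#' `alpha`) keeps the learned relation weights from collapsing onto a single
#' block.
#'
#' @param graph A [relation_graph()].
#' @param factors A factor set as produced by [init_factors()].
#' @param weights Named numeric vector of relation weights (one per block).
#' @param alpha Weight-regularization strength (default `1e5`).
#' @return The objective value.
#' @export
fusion_objective <- function(graph, factors, weights, alpha = 1e5) {
  H <- block_residuals(graph, factors)
  w <- weights[names(H)]
  if (anyNA(w)) abort("`weights` must be named with one entry per relation.")
  sum(w * H) + alpha * sum(w^2)
}

# Relations incident to each entity type, with orientation.
incident_blocks <- function(graph) {
  out <- stats::setNames(vector("list", length(graph$catalogs)), graph_types(graph))
  for (key in names(graph$relations)) {
    pair <- split_relation_key(key)
    out[[pair[1L]]] <- c(out[[pair[1L]]], list(list(key = key, transposed = FALSE)))
    out[[pair[2L]]] <- c(out[[pair[2L]]], list(list(key = key, transposed = TRUE)))
  }
  out
}

# Clamp requested ranks to axis sizes, warning when clamping occurs.
resolve_ranks <- function(graph, ranks) {
  types <- graph_types(graph)
  missing <- setdiff(types, names(ranks))
  if (length(missing) > 0L) {
    abort(sprintf("`ranks` is missing entity type(s): %s.", paste(missing, collapse = ", ")))
  }
  out <- vapply(types, function(ty) {
    k <- as.integer(ranks[[ty]])
    n <- length(graph$catalogs[[ty]])
    if (k > n) {
      warn(sprintf("rank %d for '%s' exceeds axis size %d; clamped.", k, ty, n))
      k <- n
    }
    if (k < 1L) abort(sprintf("rank for '%s' must be >= 1.", ty))
    k
  }, integer(1L))
  stats::setNames(out, types)
}

# Least-squares core given fixed factors: argmin_S ||R - Gi S Gj'||_F^2.
ls_core <- function(R, Gi, Gj) {
  MASS::ginv(crossprod(Gi)) %*% crossprod(Gi, R %*% Gj) %*% MASS::ginv(crossprod(Gj))
}

# Non-negative basis of size k from the top singular vectors of `concat`
# (NNDSVD-style): the positive and negative parts of each singular vector
# are separately valid non-negative directions; rank candidates by singular
# value times part norm and accept greedily, skipping candidates that are
# (numerically) linear combinations of those already accepted. For data
# whose column space is spanned by disjointly supported non-negative
# vectors (e.g. cluster indicators) this recovers the exact span.
nonneg_svd_basis <- function(concat, k, epsilon) {
  kk <- min(k, dim(concat))
  sv <- svd(concat, nu = kk, nv = 0L)
  cand <- list()
  score <- numeric(0)
  for (i in seq_len(kk)) {
    u <- sv$u[, i]
    for (part in list(pmax(u, 0), pmax(-u, 0))) {
      nrm <- sqrt(sum(part^2))
      if (nrm > 1e-12) {
        cand[[length(cand) + 1L]] <- part
        score <- c(score, sv$d[i] * nrm)
      }
    }
  }
  G <- matrix(epsilon, nrow(concat), k)
  basis <- matrix(0, nrow(concat), 0L) # orthonormal, tracks accepted span
  col <- 0L
  for (i in order(score, decreasing = TRUE)) {
    if (col >= k) break
    v <- cand[[i]]
    resid <- v - basis %*% crossprod(basis, v)
    rn <- sqrt(sum(resid^2))
    if (rn > 1e-8 * sqrt(sum(v^2))) {
      col <- col + 1L
      G[, col] <- v
      basis <- cbind(basis, resid / rn)
    }
  }
  pmax(G, epsilon)
}

#' Initialize factors by truncated SVD
#'
#' For each entity type the factor `G_i` is a non-negative basis extracted
#' from the top singular vectors of the horizontal concatenation of all
#' blocks incident to that type (blocks where the type indexes columns enter
#' transposed): the positive and negative parts of each singular vector are
#' taken as candidate directions, ranked by singular value times part norm,
#' and accepted greedily up to `k_i` linearly independent columns, floored
#' at `epsilon` to satisfy the non-negativity constraint. Each core `S_ij`
#' is then the least-squares minimizer of the block residual given the
#' factors. The initialization is deterministic.
#'
#' @param graph A [relation_graph()].
#' @param ranks Named integer vector, one rank per entity type. Ranks above
#'   an axis size are clamped with a warning.
#' @param epsilon Non-negativity floor applied to `G` (default `1e-12`).
#' @return A list with elements `G` (per-type factor matrices) and `S`
#'   (per-relation core matrices).
#' @export
init_factors <- function(graph, ranks, epsilon = 1e-12) {
  ranks <- resolve_ranks(graph, ranks)
  incident <- incident_blocks(graph)
  G <- lapply(graph_types(graph), function(ty) {
    blocks <- incident[[ty]]
    if (length(blocks) == 0L) {
      abort(sprintf("entity type '%s' has no incident relations.", ty))
    }
    mats <- lapply(blocks, function(b) {
      rel <- graph$relations[[b$key]]
      if (b$transposed) t(rel) else rel
    })
    concat <- do.call(cbind, mats)
    nonneg_svd_basis(concat, ranks[[ty]], epsilon)
  })
  names(G) <- graph_types(graph)
  S <- lapply(names(graph$relations), function(key) {
    pair <- split_relation_key(key)
    ls_core(graph$relations[[key]], G[[pair[1L]]], G[[pair[2L]]])
  })
  names(S) <- names(graph$relations)
  list(G = G, S = S)
}

#' One alternating sweep over cores and factors
#'
#' Updates every core `S_ij` by weighted least squares given the factors,
#' then every factor `G_i` by a multiplicative non-negative update that
#' aggregates all incident blocks with their relation weights. Every
#' sub-update is guarded: a candidate that would increase the (weighted)
#' objective contribution of the blocks it touches is rejected and the
#' previous value kept, so the objective trace is non-increasing by
#' construction.
#'
#' @inheritParams fusion_objective
#' @param epsilon Non-negativity floor for `G`.
#' @return The updated factor set.
#' @export
update_factors <- function(factors, graph, weights, alpha = 1e5, epsilon = 1e-12) {
  keys <- names(graph$relations)
  w <- weights[keys]
  if (anyNA(w)) abort("`weights` must be named with one entry per relation.")
  H <- block_residuals(graph, factors)

  # Core sweep: exact minimizer per block, so H can only decrease.
  for (key in keys) {
    pair <- split_relation_key(key)
    Gi <- factors$G[[pair[1L]]]
    Gj <- factors$G[[pair[2L]]]
    S_new <- ls_core(graph$relations[[key]], Gi, Gj)
    if (!all(is.finite(S_new))) {
      abort(sprintf("non-finite core update for relation '%s'.", key))
    }
    h_new <- reconstruction_residual(graph$relations[[key]], Gi, S_new, Gj)
    if (w[[key]] * h_new <= w[[key]] * H[[key]] + 1e-12 * max(1, H[[key]])) {
      factors$S[[key]] <- S_new
      H[[key]] <- h_new
    }
  }

  # Factor sweep: multiplicative update per entity type, objective-guarded.
  incident <- incident_blocks(graph)
  for (ty in graph_types(graph)) {
    blocks <- incident[[ty]]
    G <- factors$G[[ty]]
    A <- matrix(0, nrow(G), ncol(G))
    B <- matrix(0, ncol(G), ncol(G))
    for (b in blocks) {
      pair <- split_relation_key(b$key)
      wk <- w[[b$key]]
      if (wk == 0) next
      if (b$transposed) {
        R <- t(graph$relations[[b$key]])
        Gother <- factors$G[[pair[1L]]]
        S <- t(factors$S[[b$key]])
      } else {
        R <- graph$relations[[b$key]]
        Gother <- factors$G[[pair[2L]]]
        S <- factors$S[[b$key]]
      }
      A <- A + wk * (R %*% Gother %*% t(S))
      B <- B + wk * (S %*% crossprod(Gother) %*% t(S))
    }
    Ap <- pmax(A, 0); An <- pmax(-A, 0)
    Bp <- pmax(B, 0); Bn <- pmax(-B, 0)
    denom <- An + G %*% Bp
    numer <- Ap + G %*% Bn
    G_new <- G * sqrt(numer / (denom + 1e-12))
    G_new[denom <= 0 & numer <= 0] <- G[denom <= 0 & numer <= 0]
    G_new <- pmax(G_new, epsilon)
    if (!all(is.finite(G_new))) {
      abort(sprintf("non-finite factor update for entity type '%s'.", ty))
    }
    obj_old <- 0
    obj_new <- 0
    h_cand <- H
    for (b in blocks) {
      pair <- split_relation_key(b$key)
      Gi <- if (pair[1L] == ty) G_new else factors$G[[pair[1L]]]
      Gj <- if (pair[2L] == ty) G_new else factors$G[[pair[2L]]]
      h <- reconstruction_residual(graph$relations[[b$key]], Gi, factors$S[[b$key]], Gj)
      obj_old <- obj_old + w[[b$key]] * H[[b$key]]
      obj_new <- obj_new + w[[b$key]] * h
      h_cand[[b$key]] <- h
    }
    if (obj_new <= obj_old + 1e-12 * max(1, obj_old)) {
      factors$G[[ty]] <- G_new
      H <- h_cand
    }
  }
  factors
}

#' Learn relation weights by exact water-filling
#'
#' Minimizes `sum_ij w_ij H_ij + alpha * sum_ij w_ij^2` over the probability
#' simplex. The stationarity condition gives `w_ij = max(gamma - H_ij, 0) /
#' (2 alpha)` where the Lagrange multiplier `gamma` is found in closed form:
#' sort the residuals ascending and take the largest active-set size `m`
#' whose candidate `gamma_m = (2 alpha + sum of the m smallest H) / m`
#' strictly exceeds the m-th smallest residual. Relations outside the active
#' set get weight exactly 0.
#'
#' @param H Named non-negative numeric vector of squared residuals, one per
#'   relation.
#' @param alpha Weight-regularization strength (> 0).
#' @return A list with `w` (named weights on the simplex), `gamma` (the
#'   multiplier at the solution) and `H` (the input residuals).
#' @export
update_weights <- function(H, alpha = 1e5) {
  h <- as.numeric(H)
  if (length(h) == 0L) abort("`H` is empty: at least one relation is required.")
  if (anyNA(h) || any(h < 0)) abort("residuals must be non-negative and finite.")
  if (!is.numeric(alpha) || alpha <= 0) abort("`alpha` must be > 0.")
  ord <- order(h)
  hs <- h[ord]
  m_seq <- seq_along(hs)
  gamma_m <- (2 * alpha + cumsum(hs)) / m_seq
  active <- which(gamma_m > hs)
  m <- max(active)
  gamma <- gamma_m[m]
  w <- pmax(gamma - h, 0) / (2 * alpha)
  w <- w / sum(w) # remove float rounding; exact sum is 1 by construction
  names(w) <- names(H)
  list(w = w, gamma = gamma, H = H)
}

#' Fit the weighted collective tri-factorization model
#'
#' Alternates [update_factors()] (cores by least squares, factors by guarded
#' multiplicative updates) and [update_weights()] (exact water-filling on the
#' simplex) from the SVD initialization until the relative objective change
#' drops below `tol` or `max_iter` sweeps have run. Weights restart from
#' uniform at every fit so repeated fits (e.g. across CV folds) are
#' independent. The whole procedure is deterministic; `seed` is recorded for
#' provenance of the surrounding pipeline.
#'
#' @param graph A [relation_graph()].
#' @param ranks Named integer vector of low-rank sizes, one per entity type
#'   (the tunable `k` of the model). Values above an axis size are clamped
#'   with a warning.
#' @param alpha Weight-regularization strength (default `1e5`).
#' @param max_iter Maximum number of alternating sweeps (default 200).
#' @param tol Relative objective-change tolerance for convergence
#'   (default `1e-6`).
#' @param seed Integer recorded in the result.
#' @param epsilon Non-negativity floor for the factors (default `1e-12`).
#' @return A `trifuse_fit` object: factors, weights, `objective_trace`,
#'   `converged`, iteration count, the resolved configuration and the graph.
#' @export
fit_trifuse <- function(graph, ranks, alpha = 1e5, max_iter = 200L, tol = 1e-6,
                        seed = 1L, epsilon = 1e-12) {
  stopifnot(inherits(graph, "relation_graph"))
  if (tol < 0) abort("`tol` must be >= 0.")
  ranks <- resolve_ranks(graph, ranks)
  factors <- init_factors(graph, ranks, epsilon = epsilon)
  keys <- names(graph$relations)
  w <- stats::setNames(rep(1 / length(keys), length(keys)), keys)
  weights <- list(w = w, gamma = NA_real_, H = block_residuals(graph, factors))

  trace <- fusion_objective(graph, factors, weights$w, alpha)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    factors <- update_factors(factors, graph, weights$w, alpha = alpha, epsilon = epsilon)
    H <- block_residuals(graph, factors)
    weights <- update_weights(H, alpha)
    obj <- sum(weights$w * H) + alpha * sum(weights$w^2)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (abs(prev - obj) <= tol * max(abs(prev), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      factors = factors,
      weights = weights,
      objective_trace = trace,
      converged = converged,
      n_iter = iter,
      ranks = ranks,
      alpha = alpha,
      tol = tol,
      seed = seed,
      epsilon = epsilon,
      graph = graph
    ),
    class = "trifuse_fit"
  )
}

#' @export
print.trifuse_fit <- function(x, ...) {
  cat(sprintf(
    "<trifuse_fit> %d blocks, %d sweeps (%s), objective %.6g\n",
    length(x$graph$relations), x$n_iter,
    if (x$converged) "converged" else "max_iter reached",
    x$objective_trace[length(x$objective_trace)]
  ))
  w <- sort(x$weights$w, decreasing = TRUE)
  cat("  weights:", paste(sprintf("%s=%.3g", names(w), w), collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct a relation block from the fitted factors
#'
#' Returns the dense score matrix `G_i S_ij G_j'`. For the target block this
#' is the ranking used to score unobserved pairs (including cells that are 0
#' in the observed data).
#'
#' @param fit A `trifuse_fit`.
#' @param key Relation key; defaults to the target block.
#' @return A numeric matrix with catalog dimnames.
#' @export
reconstruct <- function(fit, key = NULL) {
  stopifnot(inherits(fit, "trifuse_fit"))
  key <- key %||% fit$graph$target_key
  if (!key %in% names(fit$factors$S)) {
    abort(sprintf("unknown relation key '%s'.", key))
  }
  pair <- split_relation_key(key)
  out <- fit$factors$G[[pair[1L]]] %*% fit$factors$S[[key]] %*% t(fit$factors$G[[pair[2L]]])
  dimnames(out) <- dimnames(fit$graph$relations[[key]])
  out
}

#' Tidy per-cell scores of the target block
#'
#' @param fit A `trifuse_fit`.
#' @return A tibble with one row per target cell: the two identifier columns
#'   (named after the entity types), the reconstructed `score`, and the
#'   observed `label` in the training graph.
#' @export
score_target <- function(fit) {
  stopifnot(inherits(fit, "trifuse_fit"))
  scores <- reconstruct(fit)
  observed <- target_matrix(fit$graph)
  pair <- split_relation_key(fit$graph$target_key)
  tibble(
    !!pair[1L] := rep(rownames(scores), times = ncol(scores)),
    !!pair[2L] := rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    label = as.vector(observed)
  )
}

#' @describeIn fit_trifuse Tidy the fitted relation weights: one row per
#'   block with its learned weight and squared residual.
#' @param x A `trifuse_fit`.
#' @param ... Unused.
#' @method tidy trifuse_fit
#' @export
tidy.trifuse_fit <- function(x, ...) {
  keys <- names(x$weights$w)
  pairs <- t(vapply(keys, split_relation_key, character(2L)))
  tibble(
    relation = keys,
    source_type = pairs[, 1L],
    target_type = pairs[, 2L],
    weight = unname(x$weights$w),
    residual = unname(x$weights$H[keys])
  )
}

#' @describeIn fit_trifuse One-row model summary.
#' @method glance trifuse_fit
#' @export
glance.trifuse_fit <- function(x, ...) {
  tibble(
    objective = x$objective_trace[length(x$objective_trace)],
    n_iter = x$n_iter,
    converged = x$converged,
    alpha = x$alpha,
    tol = x$tol,
    gamma = x$weights$gamma,
    seed = x$seed
  )
}

#' @describeIn fit_trifuse Plot the objective trace across sweeps.
#' @param object A `trifuse_fit`.
#' @method autoplot trifuse_fit
#' @export
autoplot.trifuse_fit <- function(object, ...) {
  df <- tibble(sweep = seq_along(object$objective_trace) - 1L,
               objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "sweep", y = "weighted objective",
                  title = "Fusion objective trace") +
    ggplot2::theme_minimal()
}
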
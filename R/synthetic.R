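#' Configuration for the planted-structure graph generator
#'
#' The generator emulates the topology of the real five-type network
#' (lncRNA, miRNA, gene, cancer, prognosis with seven relation blocks) at
#' desk scale. Structure is planted as a stochastic blockmodel: every entity
#' either joins one of `r` latent clusters (with probability given by
#' `membership_prob`) or stays unclustered, and each relation block turns on
#' a subset of cluster pairs. Blocks built this way are binary and of exact
#' rank at most `r`, so a tri-factorization at the true ranks can reconstruct
#' them perfectly — which is what makes exact-recovery and ablation
#' experiments well-posed. Cluster memberships are shared across blocks, so
#' side blocks genuinely inform the target block.
#'
#' The designated `informative_key` (default `lncRNA~miRNA`) receives a core
#' covering every lncRNA cluster, making it the channel that carries lncRNA
#' cluster identity; the other lncRNA block (`lncRNA~gene`) is sparse enough
#' to cover only about one cluster, so removing the informative block removes
#' most of the usable signal.
#'
#' Default block densities mirror the sparsity pattern of the real data at
#' reduced scale: molecule-molecule blocks sparse, cancer-indexed blocks
#' dense (in the real network the miRNA-cancer block has density ~0.40 and
#' the lncRNA-cancer block ~0.11).
#'
#' @param n Named entity counts per type.
#' @param ranks Named true cluster counts (ranks) per type. Must not exceed
#'   the entity counts.
#' @param density Named target fraction of ones per relation block.
#' @param membership_prob Named probability that an entity joins any cluster.
#'   Types where `n` equals the rank and the probability is 1 get one entity
#'   per cluster (identity memberships), keeping the cancer and prognosis
#'   axes aligned.
#' @param noise Independent cell-flip probability in `[0, 0.5)` applied to
#'   every block (default 0).
#' @param informative_key Block designated to carry target-relevant signal.
#' @param holdout Fraction of target positives removed into the held-out
#'   truth list (default 0.2).
#' @param target_key The block whose cells are predicted.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = c(lncRNA = 200, miRNA = 150, gene = 300,
                                   cancer = 3, prognosis = 3),
                             ranks = c(lncRNA = 5, miRNA = 5, gene = 5,
                                       cancer = 3, prognosis = 3),
                             density = c("lncRNA~miRNA" = 0.05,
                                         "lncRNA~gene" = 0.01,
                                         "lncRNA~cancer" = 0.13,
                                         "miRNA~gene" = 0.02,
                                         "miRNA~cancer" = 0.20,
                                         "gene~cancer" = 0.15,
                                         "gene~prognosis" = 0.033),
                             membership_prob = c(lncRNA = 0.5, miRNA = 0.5,
                                                 gene = 0.5, cancer = 1,
                                                 prognosis = 1),
                             noise = 0,
                             informative_key = "lncRNA~miRNA",
                             holdout = 0.2,
                             target_key = "lncRNA~cancer",
                             seed = 1L) {
  types <- names(n)
  if (is.null(types) || !setequal(types, names(ranks)) ||
      !setequal(types, names(membership_prob))) {
    abort("`n`, `ranks` and `membership_prob` must be named over the same entity types.")
  }
  if (any(ranks[types] > n[types])) {
    abort("every rank must be <= the corresponding entity count.")
  }
  if (any(density <= 0 | density >= 1)) abort("densities must lie in (0, 1).")
  if (noise < 0 || noise >= 0.5) abort("`noise` must lie in [0, 0.5).")
  if (holdout < 0 || holdout >= 1) abort("`holdout` must lie in [0, 1).")
  for (key in c(names(density), informative_key, target_key)) {
    pair <- split_relation_key(key)
    if (!all(pair %in% types)) {
      abort(sprintf("relation key '%s' references unknown entity types.", key))
    }
  }
  if (!target_key %in% names(density)) {
    abort("`target_key` must have a density entry.")
  }
  if (!informative_key %in% names(density)) {
    abort("`informative_key` must have a density entry.")
  }
  structure(
    list(
      n = n, ranks = ranks, density = density,
      membership_prob = membership_prob, noise = noise,
      informative_key = informative_key, holdout = holdout,
      target_key = target_key, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# One-hot membership matrix: each entity joins one of r clusters w.p. q.
sample_membership <- function(n, r, q) {
  if (n == r && q == 1) {
    assign <- seq_len(n) # identity memberships keep small axes aligned
  } else {
    assign <- ifelse(runif(n) < q, sample.int(r, n, replace = TRUE), 0L)
  }
  B <- matrix(0, n, r)
  on <- which(assign > 0)
  B[cbind(on, assign[on])] <- 1
  B
}

# Deterministic spread-first ordering of cluster pairs: repeatedly take the
# largest-fraction pair among those whose clusters have been used least.
order_pairs <- function(frac) {
  ri <- nrow(frac)
  rj <- ncol(frac)
  used_i <- integer(ri)
  used_j <- integer(rj)
  pairs <- expand.grid(i = seq_len(ri), j = seq_len(rj))
  taken <- logical(nrow(pairs))
  out <- integer(0)
  for (step in seq_len(nrow(pairs))) {
    use <- used_i[pairs$i] + used_j[pairs$j]
    f <- frac[cbind(pairs$i, pairs$j)]
    score <- rank(use, ties.method = "min") * 1e6 - f - 1e-9 * seq_len(nrow(pairs))
    score[taken] <- Inf
    pick <- which.min(score)
    taken[pick] <- TRUE
    used_i[pairs$i[pick]] <- used_i[pairs$i[pick]] + 1L
    used_j[pairs$j[pick]] <- used_j[pairs$j[pick]] + 1L
    out <- c(out, pick)
  }
  pairs[out, , drop = FALSE]
}

# Greedy core selection: walk cluster pairs in spread-first order, turning a
# pair on whenever that moves the realized density closer to the target.
# `base` forces pairs on (the informative matching) before the greedy pass.
greedy_core <- function(frac, target, base = NULL) {
  M <- base %||% matrix(0, nrow(frac), ncol(frac))
  achievable <- sum(frac)
  if (target > 1.05 * achievable) {
    abort(sprintf(
      "density target %.3g unreachable: at most %.3g at the given ranks/memberships.",
      target, achievable
    ))
  }
  forced <- M == 1
  current <- sum(frac[M == 1])
  ord <- order_pairs(frac)
  for (p in seq_len(nrow(ord))) {
    i <- ord$i[p]
    j <- ord$j[p]
    if (M[i, j] == 1) next
    f <- frac[i, j]
    if (abs(current + f - target) < abs(current - target)) {
      M[i, j] <- 1
      current <- current + f
    }
  }
  # single-swap refinement: exchanging one chosen pair for one unchosen pair
  # can fix the first-fit bias toward large clusters
  repeat {
    chosen <- which(M == 1 & !forced)
    open <- which(M == 0)
    if (length(chosen) == 0L || length(open) == 0L) break
    err <- abs(current - target)
    deltas <- outer(frac[chosen], frac[open], function(a, b) abs(current - a + b - target))
    if (min(deltas) >= err - 1e-15) break
    pick <- arrayInd(which.min(deltas), dim(deltas))
    M[chosen[pick[1L]]] <- 0
    M[open[pick[2L]]] <- 1
    current <- current - frac[chosen[pick[1L]]] + frac[open[pick[2L]]]
  }
  if (sum(M) == 0) {
    # force the single pair closest to the target
    pick <- which.min(abs(frac - target))
    M[pick] <- 1
  }
  M
}

# Matching core covering every source cluster: pair large source clusters
# with small target clusters to even out block sizes.
matching_core <- function(sizes_i, sizes_j) {
  ri <- length(sizes_i)
  rj <- length(sizes_j)
  M <- matrix(0, ri, rj)
  oi <- order(sizes_i, decreasing = TRUE)
  oj <- order(sizes_j)
  for (c in seq_len(min(ri, rj))) {
    if (sizes_i[oi[c]] > 0) M[oi[c], oj[c]] <- 1
  }
  M
}

#' Generate a relation graph with planted low-rank structure
#'
#' Samples cluster memberships per entity type, builds every relation block
#' as a binary blockmodel product (exact rank at most the configured rank),
#' optionally flips cells with the configured noise rate, and removes a
#' fraction of the target positives into a held-out truth list. The held-out
#' cells are 0 in the emitted target block; they are the evaluation
#' positives a good model should up-rank.
#'
#' @param config A [synthetic_config()].
#' @return A `trifuse_sim` list: `graph` (a [relation_graph()]), `truth`
#'   (tibble of held-out positive cells), `signal` (the clean pre-noise,
#'   pre-holdout target block — the latent product an oracle may read),
#'   and the `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  types <- names(config$n)
  id_width <- max(nchar(as.character(config$n))) + 1L

  withr::with_seed(config$seed, {
    catalogs <- lapply(types, function(ty) {
      entity_catalog(sprintf("%s_%0*d", ty, id_width, seq_len(config$n[[ty]])), ty)
    })
    names(catalogs) <- types

    B <- lapply(types, function(ty) {
      sample_membership(config$n[[ty]], config$ranks[[ty]], config$membership_prob[[ty]])
    })
    names(B) <- types

    relations <- list()
    signal <- NULL
    for (key in names(config$density)) {
      pair <- split_relation_key(key)
      sizes_i <- colSums(B[[pair[1L]]])
      sizes_j <- colSums(B[[pair[2L]]])
      frac <- outer(sizes_i / config$n[[pair[1L]]], sizes_j / config$n[[pair[2L]]])
      base <- if (key == config$informative_key) {
        matching_core(sizes_i, sizes_j)
      } else {
        NULL
      }
      M <- greedy_core(frac, config$density[[key]], base = base)
      R <- B[[pair[1L]]] %*% M %*% t(B[[pair[2L]]])
      if (key == config$target_key) signal <- R
      if (config$noise > 0) {
        flips <- matrix(rbinom(length(R), 1L, config$noise), nrow(R), ncol(R))
        R <- abs(R - flips)
      }
      relations[[key]] <- R
    }

    tm <- relations[[config$target_key]]
    pos <- which(tm == 1)
    n_hold <- floor(config$holdout * length(pos))
    held <- if (n_hold > 0) sort(sample(pos, n_hold)) else integer(0)
    tm[held] <- 0
    relations[[config$target_key]] <- tm

    pair <- split_relation_key(config$target_key)
    rows <- ((held - 1L) %% nrow(tm)) + 1L
    cols <- ((held - 1L) %/% nrow(tm)) + 1L
    truth <- tibble(
      row = rows,
      col = cols,
      !!pair[1L] := as.character(catalogs[[pair[1L]]])[rows],
      !!pair[2L] := as.character(catalogs[[pair[2L]]])[cols]
    )

    graph <- relation_graph(catalogs, relations, config$target_key)
  })

  structure(
    list(graph = graph, truth = truth, signal = signal, config = config),
    class = "trifuse_sim"
  )
}

#' @export
print.trifuse_sim <- function(x, ...) {
  cat(sprintf(
    "<trifuse_sim> seed %d, %d held-out target positives\n",
    x$config$seed, nrow(x$truth)
  ))
  print(x$graph)
  invisible(x)
}

#' Recovery AUC of held-out planted positives
#'
#' Scores the target block (from a fitted model or a raw score matrix) and
#' computes the AUC of the held-out truth cells (class 1) against the cells
#' that were never positive (class 0). Cells observed as positive in the
#' emitted graph are excluded — the model trains on them.
#'
#' @param sim A `trifuse_sim` from [generate_synthetic()].
#' @param object A `trifuse_fit` fitted on `sim$graph`, or a numeric score
#'   matrix of the target block's shape.
#' @return The recovery AUC.
#' @export
recovery_auc <- function(sim, object) {
  stopifnot(inherits(sim, "trifuse_sim"))
  if (nrow(sim$truth) == 0L) {
    abort("the truth list is empty: generate with a positive holdout fraction.")
  }
  scores <- if (inherits(object, "trifuse_fit")) {
    reconstruct(object, sim$config$target_key)
  } else {
    as.matrix(object)
  }
  tm <- target_matrix(sim$graph)
  if (!all(dim(scores) == dim(tm))) {
    abort("score matrix does not match the target block's shape.")
  }
  held <- cbind(sim$truth$row, sim$truth$col)
  is_held <- matrix(FALSE, nrow(tm), ncol(tm))
  is_held[held] <- TRUE
  eval_mask <- is_held | tm == 0
  auc_score(scores[eval_mask], is_held[eval_mask] * 1)
}

#' Shuffle the target labels of a graph
#'
#' Randomly permutes the entries of the target block (preserving the number
#' of positives but destroying any structure), the null configuration under
#' which cross-validated AUC should concentrate at 0.5.
#'
#' @param graph A [relation_graph()].
#' @param seed Integer seed.
#' @return A [relation_graph()] with a shuffled target block.
#' @export
shuffle_target_labels <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "relation_graph"))
  tm <- target_matrix(graph)
  shuffled <- withr::with_seed(seed, matrix(sample(as.vector(tm)), nrow(tm), ncol(tm)))
  dimnames(shuffled) <- dimnames(tm)
  relations <- graph$relations
  relations[[graph$target_key]] <- shuffled
  relation_graph(graph$catalogs, relations, graph$target_key, aligned = graph$aligned)
}
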
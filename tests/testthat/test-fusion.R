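test_that("reconstruction residual matches a brute-force double loop", {
  withr::with_seed(11, {
    R <- matrix(runif(30), 6, 5)
    Gi <- matrix(runif(12), 6, 2)
    S <- matrix(rnorm(6), 2, 3)
    Gj <- matrix(runif(15), 5, 3)
  })
  expect_equal(reconstruction_residual(R, Gi, S, Gj),
               oracle_residual(R, Gi, S, Gj), tolerance = 1e-10)

  # perfect reconstruction gives 0
  R2 <- Gi %*% S %*% t(Gj)
  expect_equal(reconstruction_residual(R2, Gi, S, Gj), 0, tolerance = 1e-18)

  # identity factors, zero core: every cell of an all-ones block contributes 1
  expect_equal(
    reconstruction_residual(matrix(1, 4, 3), diag(4), matrix(0, 4, 3), diag(3)),
    12
  )

  expect_error(
    reconstruction_residual(matrix(1, 4, 3), diag(3), matrix(0, 3, 3), diag(3)),
    "non-conformable"
  )
})

test_that("the objective equals its closed form and a brute-force sum", {
  graph <- tiny_graph(seed = 2)
  factors <- init_factors(graph, tiny_ranks)
  keys <- names(graph$relations)
  alpha <- 1e5

  # uniform weights, zero residuals: objective = alpha/m
  g_perfect <- graph
  for (key in keys) {
    pair <- strsplit(key, "~", fixed = TRUE)[[1]]
    g_perfect$relations[[key]][] <-
      factors$G[[pair[1]]] %*% factors$S[[key]] %*% t(factors$G[[pair[2]]])
  }
  w_uniform <- setNames(rep(1 / length(keys), length(keys)), keys)
  expect_equal(fusion_objective(g_perfect, factors, w_uniform, alpha),
               alpha / length(keys), tolerance = 1e-8)

  # all mass on one block: alpha + that block's residual
  w_one <- setNames(c(1, 0, 0), keys)
  h1 <- reconstruction_residual(
    graph$relations[[keys[1]]],
    factors$G[["A"]], factors$S[[keys[1]]], factors$G[["B"]]
  )
  expect_equal(fusion_objective(graph, factors, w_one, alpha), alpha + h1)

  # term-by-term brute force on random weights
  withr::with_seed(3, w <- runif(3))
  w <- setNames(w / sum(w), keys)
  brute <- alpha * sum(w^2)
  for (key in keys) {
    pair <- strsplit(key, "~", fixed = TRUE)[[1]]
    brute <- brute + w[[key]] * oracle_residual(
      graph$relations[[key]],
      factors$G[[pair[1]]], factors$S[[key]], factors$G[[pair[2]]]
    )
  }
  expect_equal(fusion_objective(graph, factors, w, alpha), brute, tolerance = 1e-8)
})

test_that("SVD initialization is exact on exactly low-rank blocks", {
  # rank-1 all-ones block: k = 1 reconstructs it exactly
  cats <- list(
    entity_catalog(sprintf("a%d", 1:4), "A"),
    entity_catalog(sprintf("b%d", 1:3), "B")
  )
  g1 <- relation_graph(cats, list("A~B" = matrix(1, 4, 3)), "A~B")
  f1 <- init_factors(g1, c(A = 1, B = 1))
  expect_lt(reconstruction_residual(g1$relations[["A~B"]],
                                    f1$G$A, f1$S[["A~B"]], f1$G$B), 1e-12)

  # planted rank-3 block from disjointly supported non-negative factors
  # (the cluster-indicator regime the generator emulates), k = 3:
  # residual below 1e-6 * ||R||_F^2
  withr::with_seed(8, {
    U <- matrix(0, 10, 3)
    U[cbind(1:10, sample(3, 10, replace = TRUE))] <- runif(10, 0.5, 1)
    V <- matrix(0, 8, 3)
    V[cbind(1:8, sample(3, 8, replace = TRUE))] <- runif(8, 0.5, 1)
  })
  R <- U %*% t(V)
  R <- R / max(R) # keep entries in [0, 1]
  cats3 <- list(
    entity_catalog(sprintf("a%d", 1:10), "A"),
    entity_catalog(sprintf("b%d", 1:8), "B")
  )
  g3 <- relation_graph(cats3, list("A~B" = R), "A~B")
  f3 <- init_factors(g3, c(A = 3, B = 3))
  expect_lt(
    reconstruction_residual(R, f3$G$A, f3$S[["A~B"]], f3$G$B),
    1e-6 * sum(R^2)
  )
})

test_that("initialization is deterministic and respects the non-negativity floor", {
  graph <- tiny_graph(seed = 4)
  f1 <- init_factors(graph, tiny_ranks)
  f2 <- init_factors(graph, tiny_ranks)
  expect_identical(f1, f2)
  expect_true(all(vapply(f1$G, function(G) all(G >= 1e-12), logical(1))))
})

test_that("requested ranks above the axis size are clamped with a warning", {
  graph <- tiny_graph(seed = 4)
  expect_warning(fit <- fit_trifuse(graph, c(A = 50, B = 2, C = 2), max_iter = 2),
                 "clamped")
  expect_identical(unname(fit$ranks["A"]), 8L)
  expect_error(
    suppressWarnings(fit_trifuse(graph, c(A = 0, B = 2, C = 2))),
    ">= 1"
  )
})

test_that("a zero graph drives the cores to zero and the objective to its floor", {
  cats <- list(
    entity_catalog(sprintf("a%d", 1:5), "A"),
    entity_catalog(sprintf("b%d", 1:4), "B")
  )
  g0 <- relation_graph(cats, list("A~B" = matrix(0, 5, 4)), "A~B")
  fit <- fit_trifuse(g0, c(A = 2, B = 2), alpha = 1e5)
  expect_lt(max(abs(fit$factors$S[["A~B"]])), 1e-6)
  # single relation: w = 1, so the floor is alpha * 1
  expect_equal(fit$objective_trace[length(fit$objective_trace)], 1e5,
               tolerance = 1e-8)
})

test_that("alternating sweeps never increase the objective and keep G non-negative", {
  graph <- tiny_graph(seed = 9)
  factors <- init_factors(graph, tiny_ranks)
  keys <- names(graph$relations)
  w <- setNames(rep(1 / 3, 3), keys)
  alpha <- 1e5
  obj <- fusion_objective(graph, factors, w, alpha)
  for (sweep in 1:50) {
    factors <- update_factors(factors, graph, w, alpha = alpha)
    H <- vapply(keys, function(key) {
      pair <- strsplit(key, "~", fixed = TRUE)[[1]]
      reconstruction_residual(graph$relations[[key]],
                              factors$G[[pair[1]]], factors$S[[key]],
                              factors$G[[pair[2]]])
    }, numeric(1))
    w <- update_weights(H, alpha)$w
    obj_new <- sum(w * H) + alpha * sum(w^2)
    expect_lte(obj_new, obj * (1 + 1e-8))
    obj <- obj_new
    expect_true(all(vapply(factors$G, function(G) all(G >= 0), logical(1))))
  }
})

test_that("fitting is deterministic and the trace is non-increasing", {
  graph <- tiny_graph(seed = 10)
  fit1 <- fit_trifuse(graph, tiny_ranks, max_iter = 60, tol = 0)
  fit2 <- fit_trifuse(graph, tiny_ranks, max_iter = 60, tol = 0)
  expect_identical(fit1$objective_trace, fit2$objective_trace)
  d <- diff(fit1$objective_trace)
  expect_true(all(d <= 1e-8 * pmax(head(fit1$objective_trace, -1), 1)))
})

test_that("a noiseless planted graph is recovered at the true ranks", {
  cfg <- small_sim_config(seed = 5, holdout = 0)
  sim <- generate_synthetic(cfg)
  fit <- fit_trifuse(sim$graph, cfg$ranks)
  baseline <- mean(vapply(sim$graph$relations, function(R) sum(R^2), numeric(1)))
  expect_lt(sum(fit$weights$w * fit$weights$H), 1e-4 * baseline)
})

test_that("reconstruct returns G_i S_ij G_j' with the right shape and names", {
  graph <- tiny_graph(seed = 12)
  fit <- fit_trifuse(graph, tiny_ranks, max_iter = 5)
  for (key in names(graph$relations)) {
    rec <- reconstruct(fit, key)
    expect_identical(dim(rec), dim(graph$relations[[key]]))
    expect_identical(dimnames(rec), dimnames(graph$relations[[key]]))
  }
  expect_error(reconstruct(fit, "A~Z"), "unknown relation key")

  # identity factors hand the core straight through
  withr::with_seed(1, S <- matrix(rnorm(20), 5, 4))
  fake <- structure(
    list(
      factors = list(G = list(P = diag(5), Q = diag(4)), S = list("P~Q" = S)),
      graph = list(relations = list("P~Q" = matrix(0, 5, 4)), target_key = "P~Q")
    ),
    class = "trifuse_fit"
  )
  expect_equal(reconstruct(fake, "P~Q"), S, ignore_attr = TRUE)

  # matches the naive triple loop on a 5x4 case
  withr::with_seed(2, {
    Gi <- matrix(runif(10), 5, 2)
    Sx <- matrix(rnorm(6), 2, 3)
    Gj <- matrix(runif(12), 4, 3)
  })
  fake$factors$G$P <- Gi
  fake$factors$G$Q <- Gj
  fake$factors$S[["P~Q"]] <- Sx
  expect_equal(unname(reconstruct(fake, "P~Q")), oracle_reconstruct(Gi, Sx, Gj),
               tolerance = 1e-12)
})

test_that("tidy and glance expose weights and convergence state", {
  graph <- tiny_graph(seed = 13)
  fit <- fit_trifuse(graph, tiny_ranks)
  td <- tidy(fit)
  expect_identical(nrow(td), 3L)
  expect_equal(sum(td$weight), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
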
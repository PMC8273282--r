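five_type_graph <- function(seed = 3) {
  # miniature of the real seven-block topology
  withr::with_seed(seed, {
    n <- c(lncRNA = 12, miRNA = 9, gene = 15, cancer = 3, prognosis = 3)
    catalogs <- lapply(names(n), function(ty) {
      entity_catalog(sprintf("%s%02d", ty, seq_len(n[[ty]])), ty)
    })
    names(catalogs) <- names(n)
    rb <- function(a, b) matrix(rbinom(n[[a]] * n[[b]], 1, 0.3), n[[a]], n[[b]])
    relations <- list(
      "lncRNA~miRNA" = rb("lncRNA", "miRNA"),
      "lncRNA~gene" = rb("lncRNA", "gene"),
      "lncRNA~cancer" = rb("lncRNA", "cancer"),
      "miRNA~gene" = rb("miRNA", "gene"),
      "miRNA~cancer" = rb("miRNA", "cancer"),
      "gene~cancer" = rb("gene", "cancer"),
      "gene~prognosis" = rb("gene", "prognosis")
    )
    relation_graph(catalogs, relations, "lncRNA~cancer")
  })
}

test_that("a seven-block graph assembles and validates", {
  graph <- five_type_graph()
  expect_s3_class(graph, "relation_graph")
  expect_length(graph$relations, 7L)
  expect_identical(graph$target_key, "lncRNA~cancer")
  # prognosis auto-aligns with the cancer axis
  expect_identical(graph$aligned, c(prognosis = "cancer"))
})

test_that("shape mismatches, duplicate pairs and missing targets are rejected", {
  cats <- list(
    entity_catalog(sprintf("a%d", 1:5), "A"),
    entity_catalog(sprintf("b%d", 1:4), "B")
  )
  expect_error(
    relation_graph(cats, list("A~B" = matrix(0, 5, 5)), "A~B"),
    "shape 5x5"
  )
  expect_error(
    relation_graph(
      cats,
      list("A~B" = matrix(0, 5, 4), "B~A" = matrix(0, 4, 5)),
      "A~B"
    ),
    "duplicate relation"
  )
  expect_error(
    relation_graph(cats, list("A~B" = matrix(0, 5, 4)), "B~A"),
    "not among the declared relations"
  )
  expect_error(
    relation_graph(cats, list("A~C" = matrix(0, 5, 4)), "A~C"),
    "undeclared entity type 'C'"
  )
})

test_that("restrict_to_cancer slices cancer-indexed blocks and nothing else", {
  graph <- five_type_graph()
  restricted <- restrict_to_cancer(graph, "cancer02")
  expect_length(restricted$catalogs$cancer, 1L)
  expect_length(restricted$catalogs$prognosis, 1L) # aligned axis sliced too
  expect_identical(dim(target_matrix(restricted)), c(12L, 1L))
  expect_identical(
    as.vector(target_matrix(restricted)),
    as.vector(target_matrix(graph)[, 2])
  )
  # blocks not indexed by cancer are untouched
  expect_identical(restricted$relations[["lncRNA~miRNA"]],
                   graph$relations[["lncRNA~miRNA"]])
  expect_identical(restricted$relations[["miRNA~gene"]],
                   graph$relations[["miRNA~gene"]])
  # idempotent
  twice <- restrict_to_cancer(restricted, "cancer02")
  expect_identical(twice$relations, restricted$relations)

  expect_error(restrict_to_cancer(graph, "no-such-cancer"), "unknown cancer")
})

test_that("dataset_summary counts positives and negatives of the target", {
  graph <- five_type_graph()
  summ <- dataset_summary(graph)
  expect_identical(nrow(summ), 7L)
  target_row <- summ[summ$relation == "lncRNA~cancer", ]
  expect_identical(target_row$positives + target_row$negatives,
                   target_row$n_source * target_row$n_target)
  expect_identical(target_row$positives, sum(target_matrix(graph) != 0))
  # non-target rows carry no positive/negative accounting
  expect_true(all(is.na(summ$positives[summ$relation != "lncRNA~cancer"])))

  # empty target: 0 positives, all cells negative
  cats <- list(
    entity_catalog(c("a1", "a2"), "A"),
    entity_catalog(c("b1", "b2", "b3"), "B")
  )
  g0 <- relation_graph(cats, list("A~B" = matrix(0, 2, 3)), "A~B")
  s0 <- dataset_summary(g0)
  expect_identical(s0$positives, 0L)
  expect_identical(s0$negatives, 6L)
})

test_that("drop_relation removes a block and prunes orphaned catalogs", {
  graph <- five_type_graph()
  dropped <- drop_relation(graph, "gene~prognosis")
  expect_false("gene~prognosis" %in% names(dropped$relations))
  expect_false("prognosis" %in% names(dropped$catalogs))
  expect_error(drop_relation(graph, "lncRNA~cancer"), "cannot be dropped")
  expect_error(drop_relation(graph, "nope~nope"), "not in the graph")
})
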
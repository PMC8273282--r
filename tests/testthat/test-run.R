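tiny_syn_section <- function(seed = 1L) {
  list(
    n = list(lncRNA = 40L, miRNA = 30L, gene = 40L, cancer = 3L, prognosis = 3L),
    ranks = list(lncRNA = 3L, miRNA = 3L, gene = 3L, cancer = 3L, prognosis = 3L),
    seed = as.integer(seed)
  )
}

tiny_run_config <- function(outdir, seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    synthetic = tiny_syn_section(seed),
    ranks = list(lncRNA = 3, miRNA = 3, gene = 3, cancer = 3, prognosis = 3),
    fit = list(alpha = 1e5, max_iter = 60, tol = 1e-6),
    cv = list(k = 4)
  )
}

test_that("run configurations round-trip through YAML and JSON", {
  config <- tiny_run_config("out", seed = 9)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(config, ypath)
  expect_identical(read_run_config(ypath)$synthetic$n$lncRNA, 40L)
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(config, jpath, auto_unbox = TRUE)
  expect_identical(read_run_config(jpath)$seed, config$seed)
  expect_identical(read_run_config(jpath)$cv$k, 4L)
  expect_error(read_run_config(withr::local_tempfile(fileext = ".csv")),
               "does not exist")
})

test_that("simulate writes files that rebuild the same graph", {
  outdir <- withr::local_tempdir()
  config <- tiny_run_config(outdir)
  sim <- run_simulate(config)
  expect_true(file.exists(file.path(outdir, "catalog_lncRNA.txt")))
  expect_true(file.exists(file.path(outdir, "edges_lncRNA_cancer.tsv")))
  expect_true(file.exists(file.path(outdir, "truth.tsv")))

  # reload one block through the relations module and compare nonzero sets
  lnc <- read_catalog(file.path(outdir, "catalog_lncRNA.txt"), "lncRNA")
  mir <- read_catalog(file.path(outdir, "catalog_miRNA.txt"), "miRNA")
  rel <- load_relation(file.path(outdir, "edges_lncRNA_miRNA.tsv"), lnc, mir)
  expect_identical(unname(rel), unname(sim$graph$relations[["lncRNA~miRNA"]]))
})

test_that("fit runs end-to-end and reruns are byte-identical", {
  outdir <- withr::local_tempdir()
  config <- tiny_run_config(outdir)
  fit <- run_fit(config)
  score_path <- file.path(outdir, "scores.tsv")
  expect_true(file.exists(score_path))
  expect_true(file.exists(file.path(outdir, "weights.tsv")))
  expect_true(file.exists(file.path(outdir, "model", "config.json")))
  scores <- readr::read_tsv(score_path, comment = "#", show_col_types = FALSE)
  expect_identical(nrow(scores), 40L * 3L)
  first <- tools::md5sum(score_path)

  outdir2 <- withr::local_tempdir()
  run_fit(tiny_run_config(outdir2))
  expect_identical(
    unname(tools::md5sum(file.path(outdir2, "scores.tsv"))),
    unname(first)
  )
})

test_that("cv and ablate commands emit their reports with provenance headers", {
  outdir <- withr::local_tempdir()
  config <- tiny_run_config(outdir)
  cv <- run_cv(config)
  expect_s3_class(cv, "trifuse_cv")
  header <- readLines(file.path(outdir, "cv_summary.tsv"), n = 2)
  expect_match(header[1], "^# seed: 1$")
  expect_match(header[2], "^# config_hash: ")

  config$ablate <- list(keys = "gene~prognosis")
  tab <- run_ablate(config)
  expect_identical(tab$dropped, c("none", "gene~prognosis"))
  expect_true(file.exists(file.path(outdir, "ablation.tsv")))
})

test_that("missing input paths fail with the offending file named", {
  outdir <- withr::local_tempdir()
  config <- list(
    seed = 1, outdir = outdir,
    target = c("lncRNA", "cancer"),
    catalogs = list(lncRNA = file.path(outdir, "nope.txt")),
    relations = list(list(source = "lncRNA", target = "cancer",
                          path = file.path(outdir, "edges.tsv"))),
    ranks = list(lncRNA = 2, cancer = 1)
  )
  expect_error(run_fit(config), "nope.txt")
})

test_that("file-based configs load, binarize and fit", {
  outdir <- withr::local_tempdir()
  lnc <- entity_catalog(sprintf("L%02d", 1:6), "lncRNA")
  can <- entity_catalog(c("breast", "lung"), "cancer")
  write_catalog(lnc, file.path(outdir, "lnc.txt"))
  write_catalog(can, file.path(outdir, "can.txt"))
  writeLines(c("L01\tbreast", "L02\tlung", "L03\tbreast", "L04\tlung"),
             file.path(outdir, "lc.tsv"))
  writeLines(c("L01\tbreast\t0.9", "L02\tlung\t0.4", "L05\tbreast\t0.51"),
             file.path(outdir, "lp.tsv"))
  config <- list(
    seed = 2, outdir = outdir,
    target = c("lncRNA", "cancer"),
    catalogs = list(
      lncRNA = file.path(outdir, "lnc.txt"),
      cancer = file.path(outdir, "can.txt")
    ),
    relations = list(
      list(source = "lncRNA", target = "cancer", path = file.path(outdir, "lc.tsv"))
    ),
    ranks = list(lncRNA = 2, cancer = 2)
  )
  graph <- config_graph(config)
  expect_identical(sum(target_matrix(graph)), 4)
  fit <- run_fit(config)
  expect_s3_class(fit, "trifuse_fit")

  # binarize option thresholds real-valued blocks on load
  config$relations <- list(
    list(source = "lncRNA", target = "cancer",
         path = file.path(outdir, "lp.tsv"), binarize = 0.5)
  )
  graph2 <- config_graph(config)
  expect_identical(sum(target_matrix(graph2)), 2) # 0.9 and 0.51 pass, 0.4 not
})
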
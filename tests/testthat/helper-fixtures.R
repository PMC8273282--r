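# Small fixture graphs built in code.

# Random binary three-type graph (not low-rank): exercises solver mechanics.
tiny_graph <- function(seed = 1, nA = 8, nB = 6, nC = 4, density = 0.3) {
  withr::with_seed(seed, {
    catalogs <- list(
      entity_catalog(sprintf("A%02d", seq_len(nA)), "A"),
      entity_catalog(sprintf("B%02d", seq_len(nB)), "B"),
      entity_catalog(sprintf("C%02d", seq_len(nC)), "C")
    )
    rand_block <- function(n, m) {
      R <- matrix(rbinom(n * m, 1, density), n, m)
      if (all(R == 0)) R[1, 1] <- 1
      if (all(R == 1)) R[1, 1] <- 0
      R
    }
    relations <- list(
      "A~B" = rand_block(nA, nB),
      "A~C" = rand_block(nA, nC),
      "B~C" = rand_block(nB, nC)
    )
    relation_graph(catalogs, relations, target_key = "A~C")
  })
}

tiny_ranks <- c(A = 2, B = 2, C = 2)

# Reduced-size synthetic configuration for quick CV-level tests.
small_sim_config <- function(seed = 1, ...) {
  synthetic_config(
    n = c(lncRNA = 80, miRNA = 60, gene = 90, cancer = 3, prognosis = 3),
    seed = seed,
    ...
  )
}

# Target-only graph at the real data's scale: 1,679 lncRNAs x 3 cancers with
# a configurable number of positives per cancer.
paper_scale_target_graph <- function(positives = c(breast = 185, lung = 179,
                                                   colorectal = 178),
                                     seed = 1) {
  lnc <- entity_catalog(sprintf("lnc%04d", seq_len(1679)), "lncRNA")
  can <- entity_catalog(names(positives), "cancer")
  tm <- matrix(0, length(lnc), length(can))
  withr::with_seed(seed, {
    for (j in seq_along(positives)) {
      tm[sample.int(length(lnc), positives[[j]]), j] <- 1
    }
  })
  relation_graph(
    list(lnc, can),
    list("lncRNA~cancer" = tm),
    target_key = "lncRNA~cancer"
  )
}
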
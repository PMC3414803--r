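# MCL engine, ICCC and the inflation sweep.

triangle_graph <- function() {
  hits <- tibble::tibble(
    query_id = c("a1", "a1", "a2", "b1", "b1", "b2"),
    subject_id = c("a2", "a3", "a3", "b2", "b3", "b3"),
    e_value = rep(1e-10, 6))
  build_graph(hits)
}

test_that("disconnected components are never merged", {
  g <- triangle_graph()
  for (r in c(1.2, 1.8, 4.0, 8.0)) {
    p <- mcl(g, r)
    expect_equal(length(p$family_sizes), 2L)
    fam <- setNames(p$assignment$famint, p$assignment$protein_id)
    expect_equal(length(unique(fam[c("a1", "a2", "a3")])), 1L)
    expect_equal(length(unique(fam[c("b1", "b2", "b3")])), 1L)
  }
})

test_that("a weak bridge between two strong cliques is cut at inflation 1.8", {
  ids <- sprintf("n%d", 0:5)
  hits <- tibble::tibble(
    query_id = c("n0", "n0", "n1", "n3", "n3", "n4", "n2"),
    subject_id = c("n1", "n2", "n2", "n4", "n5", "n5", "n3"),
    e_value = c(rep(1e-50, 6), 1e-2))
  g <- build_graph(hits, nodes = ids)
  p <- mcl(g, 1.8)
  expect_equal(length(p$family_sizes), 2L)
  fam <- setNames(p$assignment$famint, p$assignment$protein_id)
  expect_equal(length(unique(fam[c("n0", "n1", "n2")])), 1L)
  expect_equal(length(unique(fam[c("n3", "n4", "n5")])), 1L)
  # matches the independent dense reference
  ref <- oracle_mcl(famintr:::graph_matrix(g), 1.8)
  expect_true(same_partition(fam[g$nodes], ref))
})

test_that("a single node is its own singleton cluster", {
  g <- build_graph(tibble::tibble(query_id = character(),
                                  subject_id = character(),
                                  e_value = double()),
                   nodes = "solo")
  p <- mcl(g, 2.0)
  expect_equal(p$family_sizes, 1L)
  expect_equal(p$assignment$protein_id, "solo")
})

test_that("pruned MCL equals the unpruned dense reference on random graphs", {
  withr::local_seed(42)
  for (k in 1:25) {
    g <- random_similarity_graph(sample(4:10, 1))
    for (r in c(1.4, 2.0, 3.0)) {
      p <- mcl(g, r)
      fam <- setNames(p$assignment$famint, p$assignment$protein_id)[g$nodes]
      ref <- oracle_mcl(famintr:::graph_matrix(g), r)
      expect_true(same_partition(fam, ref))
      expect_lt(p$col_sum_dev, 1e-9)
    }
  }
})

test_that("higher inflation gives finer clusterings on average", {
  withr::local_seed(7)
  n_lo <- n_hi <- numeric(20)
  for (k in 1:20) {
    g <- random_similarity_graph(sample(6:12, 1), p = 0.3)
    n_lo[k] <- length(mcl(g, 1.2)$family_sizes)
    n_hi[k] <- length(mcl(g, 8.0)$family_sizes)
  }
  expect_gte(mean(n_hi), mean(n_lo))
})

test_that("mcl is deterministic under input edge order", {
  withr::local_seed(99)
  g <- random_similarity_graph(8)
  g_shuffled <- g
  ord <- sample(nrow(g$edges))
  g_shuffled$edges <- dplyr::arrange(g$edges[ord, ], from, to)
  p1 <- mcl(g, 2.0)
  p2 <- mcl(g_shuffled, 2.0)
  expect_identical(p1$assignment, p2$assignment)
})

test_that("rank_families numbers by size then smallest member id", {
  clusters <- list(c("z1", "z2", "z3"), c("m1"),
                   c("b1", "b2", "b3"), c("a9", "a8", "a7", "a6"))
  p <- rank_families(clusters)
  expect_equal(p$family_sizes, c(4L, 3L, 3L, 1L))
  fam <- setNames(p$assignment$famint, p$assignment$protein_id)
  expect_equal(unname(fam["a6"]), 0L)
  expect_equal(unname(fam["b1"]), 1L)  # "b1" < "z1" breaks the size tie
  expect_equal(unname(fam["z1"]), 2L)
  expect_equal(unname(fam["m1"]), 3L)
  p1 <- rank_families(list(c("only")))
  expect_equal(p1$assignment$famint, 0L)
})

test_that("iccc is 1 on cliques, 0 on 3-paths and 0 without size-3 clusters", {
  g <- triangle_graph()
  p <- mcl(g, 1.8)
  expect_equal(iccc(p, g), 1.0)
  expect_equal(iccc(p, g, variant = "density"), 1.0)

  # one 3-node cluster with exactly 2 edges (path): centre open, leaves deg 1
  hits <- tibble::tibble(query_id = c("a", "b"), subject_id = c("b", "c"),
                         e_value = c(1e-5, 1e-5))
  gp <- build_graph(hits)
  path_part <- rank_families(list(c("a", "b", "c")))
  expect_equal(iccc(path_part, gp), 0.0)

  tiny <- rank_families(list(c("a", "b"), "c"))
  expect_equal(iccc(tiny, gp), 0.0)
})

test_that("the default sweep grid has 35 points and selects the ICCC argmax", {
  grid <- sweep_grid()
  expect_length(grid, 35L)
  expect_equal(grid[1], 1.2)
  expect_equal(grid[35], 8.0)
  expect_equal(unique(round(diff(grid), 10)), 0.2)

  # disjoint cliques give ICCC 1 everywhere -> tie broken to lowest inflation
  g <- triangle_graph()
  sw <- inflation_sweep(g, grid = c(1.2, 1.8, 2.4))
  expect_equal(attr(sw, "selected_inflation"), 1.2)
  expect_equal(max(tidy(sw)$iccc), 1.0)

  # deterministic across reruns
  sw2 <- inflation_sweep(g, grid = c(1.2, 1.8, 2.4))
  expect_identical(tidy(sw), tidy(sw2))
  expect_identical(selected_partition(sw)$assignment,
                   selected_partition(sw2)$assignment)
})

test_that("sweep recovers a clique-planted partition", {
  withr::local_seed(3)
  ids <- sprintf("c%d_%d", rep(1:3, each = 4), rep(1:4, 3))
  truth <- rep(1:3, each = 4)
  from <- character(0); to <- character(0)
  for (cl in 1:3) {
    mem <- ids[truth == cl]
    pr <- utils::combn(mem, 2)
    from <- c(from, pr[1, ]); to <- c(to, pr[2, ])
  }
  g <- build_graph(tibble::tibble(query_id = from, subject_id = to,
                                  e_value = 10^(-runif(length(from), 20, 60))),
                   nodes = ids)
  sw <- inflation_sweep(g)
  p <- selected_partition(sw)
  fam <- setNames(p$assignment$famint, p$assignment$protein_id)[ids]
  expect_true(same_partition(fam, truth))
  expect_equal(p$iccc, 1.0)
})
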
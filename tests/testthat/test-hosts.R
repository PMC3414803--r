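# Genus grouping, shared-family edge weights, components and hub removal.

test_that("group_hosts collapses multi-strain genera and keeps singletons", {
  hosts <- c("Mycobacterium gilvum PYR-GCK", "Mycobacterium sp. KMS",
             "Gramella forsetii KT0803")
  nodes <- group_hosts(hosts)
  expect_setequal(nodes$label, c("Mycobacterium", "Gramella forsetii KT0803"))
  expect_equal(nodes$n_members[nodes$label == "Mycobacterium"], 2L)

  # a 10-host fixture with a two-strain genus and singleton genera
  fixture <- c("Cupriavidus metallidurans CH34", "Cupriavidus eutrophus H16",
               "Gramella forsetii KT0803", "Escherichia coli K-12",
               "Salmonella enterica LT2", "Pseudomonas aeruginosa PAO1",
               "Caulobacter sp. K31", "Dinoroseobacter shibae DFL12",
               "Bordetella petrii DSM12804", "Aromatoleum aromaticum EbN1")
  nodes10 <- group_hosts(fixture)
  expect_equal(nrow(nodes10), 9L)
  expect_true("Cupriavidus" %in% nodes10$label)
  expect_true("Gramella forsetii KT0803" %in% nodes10$label)

  # "Candidatus" is skipped when parsing the genus
  cand <- group_hosts(c("Candidatus Liberibacter asiaticus",
                        "Liberibacter crescens BT-1"))
  expect_equal(cand$label, "Liberibacter")

  expect_equal(nrow(group_hosts(character(0))), 0L)
})

test_that("edge weights count shared families above the size floor", {
  part <- rank_families(list(c("a1", "b1"), c("a2", "b2"), c("a3", "b3"),
                             c("a4"), c("b4")))
  prot <- tibble::tibble(
    id = c(paste0("a", 1:4), paste0("b", 1:4)),
    host = rep(c("Gramella forsetii KT0803", "Caulobacter sp. K31"),
               each = 4))
  g <- shared_family_graph(part, prot)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 3L)   # three shared families of size >= 2
  # families present in one host only contribute nothing
  part2 <- rank_families(list(c("a1", "a2"), c("b1", "b2")))
  g2 <- shared_family_graph(part2, prot)
  expect_equal(nrow(g2$edges), 0L)
})

test_that("weights equal a brute-force recount from the planted truth", {
  gs <- generate_protein_set(synth_params(seed = 4))
  part <- rank_families(split(gs$truth$protein_id, gs$truth$true_family))
  g <- shared_family_graph(part, gs$proteins)
  nodes <- g$nodes
  lab_of <- setNames(rep(nodes$label, lengths(nodes$members)),
                     unlist(nodes$members))
  sizes <- table(gs$truth$true_family)
  big <- names(sizes)[sizes >= 2]
  # brute force: for every pair of labels, count families present in both
  labs <- sort(nodes$label)
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in seq((i + 1), length(labs))) {
      cnt <- 0L
      for (f in big) {
        hosts_f <- unique(lab_of[gs$truth$host[gs$truth$true_family == f]])
        if (labs[i] %in% hosts_f && labs[j] %in% hosts_f) cnt <- cnt + 1L
      }
      w <- g$edges$weight[g$edges$from == labs[i] & g$edges$to == labs[j]]
      expect_equal(if (length(w)) w else 0L, cnt)
    }
  }
  # weight conservation: each family contributes C(k, 2) increments
  contrib <- vapply(big, function(f) {
    k <- length(unique(lab_of[gs$truth$host[gs$truth$true_family == f]]))
    choose(k, 2)
  }, numeric(1))
  expect_equal(sum(g$edges$weight), sum(contrib))
})

test_that("components match an independent union-find recomputation", {
  withr::local_seed(77)
  gs <- generate_protein_set(synth_params(seed = 5))
  part <- rank_families(split(gs$truth$protein_id, gs$truth$true_family))
  g <- shared_family_graph(part, gs$proteins)
  comp <- host_components(g)
  ref <- oracle_components(g$nodes$label, g$edges$from, g$edges$to)
  norm <- function(x) x[order(vapply(x, `[`, character(1), 1))]
  expect_equal(norm(comp), norm(ref))

  # edgeless graph: all singleton components
  lonely <- g
  lonely$edges <- g$edges[0, ]
  expect_equal(length(host_components(lonely)), nrow(g$nodes))
})

test_that("hub removal splits components as constructed", {
  star_edges <- tibble::tibble(from = "hub", to = sprintf("leaf%d", 1:4),
                               weight = 1L)
  star <- structure(list(
    nodes = tibble::tibble(label = c("hub", sprintf("leaf%d", 1:4))),
    edges = star_edges), class = "host_graph")
  imp <- hub_impact(star, "hub")
  expect_equal(imp$n_before, 1L)
  expect_equal(imp$n_after, 4L)

  path3 <- structure(list(
    nodes = tibble::tibble(label = c("a", "b", "c")),
    edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                           weight = 1L)), class = "host_graph")
  impl <- hub_impact(path3, "c")   # removing a leaf keeps one component
  expect_equal(impl$n_before, 1L)
  expect_equal(impl$n_after, 1L)

  # barbell with satellites: two bridge hubs hold five pieces together
  e <- tibble::tibble(
    from = c("c1a", "c1a", "c1b", "c2a", "c2a", "c2b",
             "bridge1", "bridge1", "bridge2", "bridge2",
             "bridge1", "bridge2"),
    to = c("c1b", "c1c", "c1c", "c2b", "c2c", "c2c",
           "c1a", "sat1", "c2a", "sat2", "bridge2", "c1a"),
    weight = 1L)
  labs <- unique(c(e$from, e$to))
  bb <- structure(list(nodes = tibble::tibble(label = labs), edges = e),
                  class = "host_graph")
  imp2 <- hub_impact(bb, c("bridge1", "bridge2"))
  expect_equal(imp2$n_before, 1L)
  # two satellite singletons plus two triangles
  expect_equal(imp2$n_after, 4L)
  expect_equal(sort(lengths(imp2$components_after)), c(1L, 1L, 3L, 3L))

  expect_error(hub_impact(star, "nope"), "unknown node label")
})
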
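# Guide trees, progressive alignment, conservation and motif detection.

test_that("guide_tree shapes follow the similarity weights", {
  two <- tibble::tibble(id = c("a", "b"), sequence = c("ACD", "ACD"))
  t2 <- guide_tree(two)
  expect_s3_class(t2, "hclust")
  expect_setequal(t2$labels, c("a", "b"))

  # w(a,b) >> w(a,c) = w(b,c) forces ((a,b),c)
  g <- build_graph(tibble::tibble(
    query_id = c("a", "a", "b"), subject_id = c("b", "c", "c"),
    e_value = c(1e-60, 1e-5, 1e-5)))
  three <- tibble::tibble(id = c("a", "b", "c"),
                          sequence = c("ACD", "ACD", "ACD"))
  t3 <- guide_tree(three, g)
  first_pair <- t3$labels[-t3$merge[1, ]]
  expect_setequal(first_pair, c("a", "b"))
})

test_that("progressive alignment is gap-free on identical inputs and round-trips", {
  mem <- tibble::tibble(id = c("a", "b", "c"),
                        sequence = rep("MKVLATTRY", 3))
  aln <- progressive_msa(mem)
  expect_false(any(grepl("-", aln$rows, fixed = TRUE)))
  expect_equal(aln$n_columns, 9L)

  # 'ACDEF' vs 'ACEF': a single gap column in the optimal global alignment
  mem2 <- tibble::tibble(id = c("x", "y"), sequence = c("ACDEF", "ACEF"))
  aln2 <- progressive_msa(mem2)
  expect_equal(aln2$n_columns, 5L)
  expect_equal(sum(strsplit(aln2$rows[["y"]], "")[[1]] == "-"), 1L)

  # round-trip: de-gapping reproduces the inputs exactly
  withr::local_seed(31)
  mem3 <- tibble::tibble(
    id = sprintf("s%d", 1:5),
    sequence = vapply(1:5, function(k) {
      base <- random_aa_string(80)
      if (k > 2) substr(base, 5, 80) else base  # ragged lengths force gaps
    }, character(1)))
  aln3 <- progressive_msa(mem3)
  for (id in mem3$id) {
    expect_equal(gsub("-", "", aln3$rows[[id]]),
                 mem3$sequence[mem3$id == id])
  }
  expect_equal(length(unique(nchar(aln3$rows))), 1L)

  expect_error(progressive_msa(tibble::tibble(id = "a", sequence = "AC-D")),
               "residue")
})

test_that("column conservation handles gaps and ties", {
  aln <- structure(list(family_index = 0L,
                        rows = c(a = "YY-F", b = "YYYF", c = "YY-Y",
                                 d = "Y-YF"),
                        n_columns = 4L), class = "msa")
  prof <- column_conservation(aln)
  expect_equal(prof$consensus[1], "Y")
  expect_equal(prof$consensus_frac[1], 1.0)
  expect_equal(prof$consensus_frac[2], 1.0)  # over non-gap rows only
  expect_equal(prof$gap_frac[2], 0.25)
  expect_equal(prof$consensus_frac[4], 0.75)
  expect_equal(prof$gap_frac[3], 0.5)
})

test_that("the motif scan finds a constructed RH...Y tetrad and labels it", {
  stem <- strrep("A", 40)
  # R..Y spacing 30 with an H anchor; the residue after H varies across
  # rows so the conserved run after R stops at the H
  spacers <- c("L", "I", "V", "F", "M")
  seqs <- paste0(stem, "RH", spacers, strrep("L", 27), "Y", "GG")
  aln <- structure(list(family_index = 0L,
                        rows = setNames(seqs, sprintf("p%d", 1:5)),
                        n_columns = nchar(seqs[1])), class = "msa")
  call <- find_catalytic_motif(aln)
  expect_true(call$found)
  expect_equal(call$label, "RH-Y")
  expect_equal(call$median_spacing, 30)
  expect_equal(call$y_conservation, 1.0)
  expect_equal(call$r_column + 30L, call$y_column)

  # degrading the Y below the conservation threshold kills the call
  seqs2 <- seqs
  seqs2[1:3] <- sub("Y(GG)$", "F\\1", seqs2[1:3])
  aln2 <- aln; aln2$rows <- setNames(seqs2, names(aln$rows))
  call2 <- find_catalytic_motif(aln2)
  expect_false(call2$found)

  # too few rows
  aln3 <- aln; aln3$rows <- aln$rows[1:3]
  expect_false(find_catalytic_motif(aln3)$found)
  expect_equal(find_catalytic_motif(aln3)$reason, "too few rows")
  expect_equal(find_catalytic_motif(aln3)$label, "no obvious one")
})

test_that("any returned motif call satisfies its own thresholds", {
  withr::local_seed(12)
  gs <- generate_protein_set(synth_params(
    n_families = 5, family_size_range = c(6, 10), n_singletons = 0,
    seq_length_range = c(220, 280), seed = 12))
  part <- rank_families(split(gs$truth$protein_id, gs$truth$true_family))
  m <- family_motifs(part, gs$proteins)
  opts <- motif_options()
  for (k in which(m$found)) {
    expect_gte(m$y_conservation[k], opts$conservation_min)
    expect_gte(m$r_conservation[k], opts$conservation_min)
    expect_true(m$median_spacing[k] >= opts$spacing_range[1] &&
                  m$median_spacing[k] <= opts$spacing_range[2])
  }
})

test_that("planted motifs are recovered within the spacing window", {
  # Exact column recovery is a statistical property of the default corpus
  # (larger families; see the acceptance suite); here small families can
  # carry chance-conserved columns, so assert the detection contract.
  gs <- generate_protein_set(synth_params(
    n_families = 6, family_size_range = c(8, 14), n_singletons = 0,
    motif_spacing_range = c(30, 30), seed = 13))
  part <- rank_families(split(gs$truth$protein_id, gs$truth$true_family))
  m <- family_motifs(part, gs$proteins)
  expect_true(all(m$found))
  expect_true(all(m$median_spacing >= 20 & m$median_spacing <= 40))
  # most families still pin the exact planted Y (ungapped coordinates)
  members <- famintr:::partition_members(part)
  exact <- vapply(seq_len(nrow(m)), function(k) {
    ids <- members[[as.character(m$famint[k])]]
    y_tr <- unique(gs$truth$motif_y[gs$truth$protein_id %in% ids])
    any(column_to_positions(m$msa[[k]], m$y_column[k]) == y_tr,
        na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(exact), 0.5)
})
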
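# Synthetic corpus generator: mutation model, planted families and motifs,
# replicon layouts with decoys, determinism.

test_that("mutate_sequence honours identity targets and protection", {
  withr::local_seed(1)
  expect_equal(mutate_sequence("ACDEF", 1.0), "ACDEF")

  seq <- paste0("R", strrep("A", 25), "Y")
  out <- mutate_sequence(seq, 1e-9, protected = c(0L, 26L))
  expect_equal(substr(out, 1, 1), "R")
  expect_equal(substr(out, 27, 27), "Y")

  # binomial concentration: observed identity within [0.66, 0.74] per seed
  base <- random_aa_string(1000)
  obs <- vapply(1:50, function(k) {
    m <- mutate_sequence(base, 0.7)
    mean(strsplit(m, "")[[1]] == strsplit(base, "")[[1]])
  }, numeric(1))
  expect_true(all(obs >= 0.66 & obs <= 0.74))

  expect_error(mutate_sequence("", 0.5), "non-empty")
  expect_error(mutate_sequence("ACD", 0.5, protected = 5L), "out of range")
})

test_that("zero-mutation families are identical and motifs are forced", {
  gs <- generate_protein_set(synth_params(
    n_families = 1, family_size_range = c(3, 3), n_singletons = 0,
    within_family_identity = 1.0, seed = 2))
  expect_equal(nrow(gs$proteins), 3L)
  expect_equal(length(unique(gs$proteins$sequence)), 1L)
  expect_equal(unique(gs$truth$true_family), 0L)

  gs2 <- generate_protein_set(synth_params(
    n_families = 3, family_size_range = c(4, 6), n_singletons = 0,
    motif_fraction = 1.0, motif_spacing_range = c(30, 30), seed = 3))
  expect_true(all(gs2$truth$motif_y - gs2$truth$motif_r == 30L))
})

test_that("motif residues are exactly R and Y at the truth positions", {
  gs <- generate_protein_set(synth_params(
    n_families = 4, family_size_range = c(5, 8), n_singletons = 0,
    within_family_identity = 0.55, seed = 4))
  with(merge(gs$proteins, gs$truth, by.x = "id", by.y = "protein_id"), {
    expect_true(all(substr(sequence, motif_r + 1, motif_r + 1) == "R"))
    expect_true(all(substr(sequence, motif_y + 1, motif_y + 1) == "Y"))
  })
})

test_that("within-family identity is high and between-family identity low", {
  gs <- generate_protein_set(synth_params(seed = 1))
  withr::local_seed(10)
  truth <- setNames(gs$truth$true_family, gs$truth$protein_id)
  fams <- split(gs$proteins$id, truth[gs$proteins$id])
  fams <- fams[lengths(fams) >= 2]
  seqs <- setNames(gs$proteins$sequence, gs$proteins$id)
  within <- vapply(1:50, function(k) {
    f <- sample(fams, 1)[[1]]
    pr <- sample(f, 2)
    pairwise_identity(seqs[[pr[1]]], seqs[[pr[2]]])
  }, numeric(1))
  between <- vapply(1:50, function(k) {
    fs <- sample(names(fams), 2)
    pairwise_identity(seqs[[sample(fams[[fs[1]]], 1)]],
                      seqs[[sample(fams[[fs[2]]], 1)]])
  }, numeric(1))
  expect_true(all(within >= 0.5))
  expect_true(all(between <= 0.2))
})

test_that("the generator is byte-identical under the same seed", {
  ps <- synth_params(n_families = 2, family_size_range = c(4, 6),
                     n_singletons = 3, seq_length_range = c(100, 140),
                     seed = 8)
  d1 <- withr::local_tempdir()
  for (run in c("a", "b")) {
    gs <- generate_protein_set(ps)
    write_fasta(gs$proteins, file.path(d1, paste0(run, ".fasta")))
    write_metadata_tsv(gs$proteins, file.path(d1, paste0(run, ".tsv")))
  }
  expect_identical(unname(tools::md5sum(file.path(d1, "a.fasta"))),
                   unname(tools::md5sum(file.path(d1, "b.fasta"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "a.tsv"))),
                   unname(tools::md5sum(file.path(d1, "b.tsv"))))
  # and a different seed changes the output
  gs3 <- generate_protein_set(synth_params(
    n_families = 2, family_size_range = c(4, 6), n_singletons = 3,
    seq_length_range = c(100, 140), seed = 9))
  expect_false(identical(gs3$proteins$sequence[1],
                         generate_protein_set(ps)$proteins$sequence[1]))
})

test_that("planted replicon elements obey the layout rules", {
  rep1 <- generate_annotated_replicon(list(list(type = "RIT")), seed = 5)
  f <- rep1$features[rep1$features$is_tbssr, ]
  expect_equal(nrow(f), 3L)
  expect_equal(length(unique(f$strand)), 1L)
  o1 <- f$end[1] - f$start[2]
  o2 <- f$end[2] - f$start[3]
  expect_true(all(c(o1, o2) >= 4 & c(o1, o2) <= 8))
  span <- max(f$end) - min(f$start)
  expect_true(span >= 3300 && span <= 3700)

  rep2 <- generate_annotated_replicon(list(list(type = "Tn554")), seed = 6)
  tb <- rep2$features[rep2$features$is_tbssr, ]
  expect_true(any(tb$product_len >= 611 & tb$product_len <= 828))
  long <- tb[tb$product_len >= 611, ]
  expect_true(all((long$end - long$start) / 3 - 1 - long$product_len == 0))

  # a strand decoy leaves the planted-truth table empty
  rep3 <- generate_annotated_replicon(
    list(list(type = "RIT", decoy = "strand")), seed = 7)
  expect_equal(nrow(rep3$planted), 0L)
  expect_equal(rep3$decoys$violation, "strand")
})

test_that("each decoy violates at least one detector predicate", {
  suite <- synth_replicon_suite(seed = 1)
  calls <- detect_elements(suite$features, bim_partner_famint = 45L)
  called_sets <- lapply(calls$members, sort)
  for (k in seq_len(nrow(suite$decoys))) {
    decoy_members <- sort(suite$decoys$members[[k]])
    hit <- any(vapply(called_sets, function(s) {
      length(intersect(s, decoy_members)) >= 2
    }, logical(1)))
    expect_false(hit)
  }
})

test_that("incompatible identity/length targets raise a parameter error", {
  expect_error(generate_protein_set(synth_params(
    n_families = 1, family_size_range = c(3, 3), n_singletons = 0,
    seq_length_range = c(40, 40), within_family_identity = 0.1,
    motif_spacing_range = c(32, 32), seed = 1)),
    "incompatible")
})
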
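# Gene-context detectors for RIT, Tn554-like and BIM elements, and the
# repeat scanner.

tb_feat <- function(start, aa, strand = "+", id, tbssr = TRUE, fam = NA) {
  tibble::tibble(replicon = "r1", start = as.integer(start),
                 end = as.integer(start + 3 * (aa + 1)), strand = strand,
                 id = id, product_len = as.integer(aa), is_tbssr = tbssr,
                 famint = as.integer(fam))
}

rit_trio <- function(o1 = 5L, o2 = 7L, aa = c(383, 383, 383),
                     strands = c("+", "+", "+")) {
  f1 <- tb_feat(1000, aa[1], strands[1], "g1")
  f2 <- tb_feat(f1$end - o1, aa[2], strands[2], "g2")
  f3 <- tb_feat(f2$end - o2, aa[3], strands[3], "g3")
  dplyr::bind_rows(f1, f2, f3)
}

test_that("find_rit applies the overlap, span and strand rules", {
  trio <- rit_trio()       # overlaps 5 and 7, span 3,440
  calls <- find_rit(trio)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$members[[1]], c("g1", "g2", "g3"))
  d <- calls$diagnostics[[1]]
  expect_equal(c(d$overlap_ab, d$overlap_bc), c(5L, 7L))
  expect_true(d$span >= 3300 && d$span <= 3700)

  # middle gene on the opposite strand
  expect_equal(nrow(find_rit(rit_trio(strands = c("+", "-", "+")))), 0L)
  # overlap out of range
  expect_equal(nrow(find_rit(rit_trio(o1 = 12L))), 0L)
  # gap instead of overlap
  expect_equal(nrow(find_rit(rit_trio(o1 = -50L))), 0L)
  # span out of range
  expect_equal(nrow(find_rit(rit_trio(aa = c(280, 280, 280)))), 0L)
  # minus-strand trio: members reported in reversed (transcription) order
  minus <- rit_trio(strands = c("-", "-", "-"))
  calls_m <- find_rit(minus)
  expect_equal(calls_m$members[[1]], c("g3", "g2", "g1"))

  expect_error(find_rit(trio[c(2, 1, 3), ]), "sorted")
})

test_that("find_tn554_like pairs a long and short TBSSR and attaches TnpC", {
  f1 <- tb_feat(100, 700, "+", "long")
  f2 <- tb_feat(f1$end + 80, 350, "+", "short")
  f3 <- tb_feat(f2$end + 60, 200, "+", "tnpc", tbssr = FALSE)
  feats <- dplyr::bind_rows(f1, f2, f3)
  calls <- find_tn554_like(feats)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$has_tnpC)
  expect_equal(calls$members[[1]], c("long", "short", "tnpc"))
  d <- calls$diagnostics[[1]]
  expect_equal(d$n_extension, 350L)
  expect_false(d$long_extension_flag)  # 350 < 400

  # without the TnpC gene the tandem is still called
  calls2 <- find_tn554_like(dplyr::bind_rows(f1, f2))
  expect_equal(nrow(calls2), 1L)
  expect_false(calls2$has_tnpC)

  # opposite strands
  f2b <- tb_feat(f1$end + 80, 350, "-", "short")
  expect_equal(nrow(find_tn554_like(dplyr::bind_rows(f1, f2b))), 0L)

  # long member below the 611 aa bound
  f1c <- tb_feat(100, 500, "+", "long")
  f2c <- tb_feat(f1c$end + 80, 350, "+", "short")
  expect_equal(nrow(find_tn554_like(dplyr::bind_rows(f1c, f2c))), 0L)

  # an 820 aa member trips the long N-extension flag
  f1d <- tb_feat(100, 820, "+", "long")
  f2d <- tb_feat(f1d$end + 80, 350, "+", "short")
  d2 <- find_tn554_like(dplyr::bind_rows(f1d, f2d))$diagnostics[[1]]
  expect_true(d2$long_extension_flag)
})

test_that("find_bim requires the partner family within the gap limit", {
  f1 <- tb_feat(100, 300, "+", "tb")
  f2 <- tb_feat(f1$end + 100, 250, "+", "partner", tbssr = FALSE, fam = 45)
  feats <- dplyr::bind_rows(f1, f2)
  calls <- find_bim(feats, partner_famint = 45L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$members[[1]], c("tb", "partner"))

  far <- dplyr::bind_rows(f1, tb_feat(f1$end + 5000, 250, "+", "partner",
                                      tbssr = FALSE, fam = 45))
  expect_equal(nrow(find_bim(far, partner_famint = 45L)), 0L)

  expect_error(find_bim(feats), "partner_famint")
})

test_that("the synthetic suite is detected at sensitivity and precision 1", {
  suite <- synth_replicon_suite(seed = 1)
  calls <- detect_elements(suite$features, bim_partner_famint = 45L)
  validate_element_calls(calls)

  truth_sets <- lapply(suite$planted$members, sort)
  called_sets <- lapply(calls$members, sort)
  matched <- function(s, pool) {
    any(vapply(pool, function(p) length(intersect(p, s)) >= 2, logical(1)))
  }
  # sensitivity: every planted element recovered
  expect_true(all(vapply(truth_sets, matched, logical(1),
                         pool = called_sets)))
  # precision: every call corresponds to a planted element, none to a decoy
  expect_true(all(vapply(called_sets, matched, logical(1),
                         pool = truth_sets)))
  expect_equal(nrow(calls), nrow(suite$planted))
})

test_that("detection is mirror-symmetric under reverse complementation", {
  suite <- synth_replicon_suite(seed = 2)
  calls <- detect_elements(suite$features, bim_partner_famint = 45L)
  mirrored <- mirror_features(suite$features, suite$length)
  calls_m <- detect_elements(mirrored, bim_partner_famint = 45L)
  expect_equal(nrow(calls_m), nrow(calls))
  key <- function(cc) {
    sort(vapply(cc$members, function(m) paste(sort(m), collapse = ","),
                character(1)))
  }
  expect_equal(key(calls_m), key(calls))
  # strands invert
  s1 <- calls[order(vapply(calls$members, function(m)
    paste(sort(m), collapse = ","), character(1))), ]
  s2 <- calls_m[order(vapply(calls_m$members, function(m)
    paste(sort(m), collapse = ","), character(1))), ]
  expect_true(all(s1$strand != s2$strand))
})

test_that("scan_repeats finds planted inverted repeats and stays quiet on noise", {
  withr::local_seed(14)
  bases <- c("A", "C", "G", "T")
  core <- paste(sample(bases, 28, TRUE), collapse = "")
  left <- paste(sample(bases, 300, TRUE), collapse = "")
  mid <- paste(sample(bases, 400, TRUE), collapse = "")
  right <- paste(sample(bases, 200, TRUE), collapse = "")
  seq <- paste0(left, core, mid, famintr:::revcomp(core), right)
  hits <- scan_repeats(seq, min_len = 9)
  inv <- hits[hits$type == "inverted", ]
  expect_gte(nrow(inv), 1L)
  expect_true(any(inv$length >= 28 & abs(inv$pos1 - 300) <= 2))

  # homopolymers are suppressed by the low-complexity filter
  homo <- scan_repeats(strrep("A", 100))
  expect_equal(nrow(homo), 0L)
  flagged <- scan_repeats(strrep("A", 100), drop_low_complexity = FALSE)
  expect_true(all(flagged$low_complexity))

  # empirical null: random 1 kb sequences rarely contain 12-mers twice
  n_hit <- vapply(1:40, function(k) {
    s <- paste(sample(bases, 1000, TRUE), collapse = "")
    nrow(scan_repeats(s, min_len = 12))
  }, integer(1))
  expect_gte(mean(n_hit == 0), 0.95)
})
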
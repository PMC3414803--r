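# Rule-based detection of composite recombinase elements from gene features.
# Coordinates are 0-based half-open; overlaps and gaps are computed on the
# nucleotide CDS intervals.

#' Rules for composite-element detection
#'
#' @param rit_overlap_range Required pairwise CDS overlap between adjacent
#'   RIT genes, in bp (default 4-8).
#' @param rit_span_range Required total RIT span in bp (default 3300-3700,
#'   i.e. "around 3,500").
#' @param rit_require_same_strand Require the three RIT genes co-oriented.
#' @param tn554_long_range Length of the long (TnpA-like) TBSSR in aa.
#' @param tn554_short_range Length of the short (TnpB-like) TBSSR in aa
#'   (default 275-425, "around 350").
#' @param tn554_max_gap Maximum intergenic gap in the tandem and to the
#'   putative TnpC, in bp.
#' @param tn554_require_same_strand Require the tandem co-oriented.
#' @param long_next_extension_min N-terminal extension (aa) above which the
#'   long member is flagged (default 400).
#' @param bim_partner_max_gap Maximum TBSSR-to-partner gap in bp.
#' @export
element_rules <- function(rit_overlap_range = c(4L, 8L),
                          rit_span_range = c(3300L, 3700L),
                          rit_require_same_strand = TRUE,
                          tn554_long_range = c(611L, 828L),
                          tn554_short_range = c(275L, 425L),
                          tn554_max_gap = 500L,
                          tn554_require_same_strand = TRUE,
                          long_next_extension_min = 400L,
                          bim_partner_max_gap = 300L) {
  rngs <- list(rit_overlap_range, rit_span_range, tn554_long_range,
               tn554_short_range)
  if (any(vapply(rngs, function(r) r[1] > r[2], logical(1)))) {
    abort("all ranges must be ordered")
  }
  list(rit_overlap_range = as.integer(rit_overlap_range),
       rit_span_range = as.integer(rit_span_range),
       rit_require_same_strand = rit_require_same_strand,
       tn554_long_range = as.integer(tn554_long_range),
       tn554_short_range = as.integer(tn554_short_range),
       tn554_max_gap = as.integer(tn554_max_gap),
       tn554_require_same_strand = tn554_require_same_strand,
       long_next_extension_min = as.integer(long_next_extension_min),
       bim_partner_max_gap = as.integer(bim_partner_max_gap))
}

cds_overlap <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))
cds_gap <- function(e1, s2) pmax(0L, s2 - e1)

check_sorted <- function(features) {
  ok <- features |>
    group_by(.data$replicon) |>
    summarise(sorted = !is.unsorted(.data$start), .groups = "drop")
  if (!all(ok$sorted)) abort("features must be sorted by start within replicon")
  invisible(features)
}

empty_calls <- function() {
  tibble(type = character(), replicon = character(), start = integer(),
         end = integer(), span = integer(), strand = character(),
         members = list(), has_tnpC = logical(), conflict = logical(),
         diagnostics = list())
}

#' Detect RIT elements (recombinases in trio)
#'
#' Scans every window of three consecutive TBSSR gene features on one
#' replicon; a window is called when the genes are co-oriented (if
#' required), both pairwise CDS overlaps lie in `rit_overlap_range` and the
#' total span lies in `rit_span_range`.  Members are reported A/B/C in
#' genomic order on the plus strand and reversed on the minus strand.
#' Windows sharing a gene are all reported, flagged with `conflict = TRUE`.
#'
#' @param features Gene feature tibble (`replicon`, `start`, `end`,
#'   `strand`, `id`, `product_len`, `is_tbssr`, `famint`), sorted by start
#'   within each replicon (error otherwise).
#' @param rules [element_rules()].
#' @return Element-call tibble: `type`, `replicon`, `start`, `end`, `span`,
#'   `strand`, `members` (list column, A/B/C order), `has_tnpC` (NA),
#'   `conflict`, `diagnostics` (list column).
#' @export
find_rit <- function(features, rules = element_rules()) {
  check_sorted(features)
  calls <- list()
  for (rep_df in split(features, features$replicon)) {
    n <- nrow(rep_df)
    if (n < 3) next
    for (i in seq_len(n - 2)) {
      w <- rep_df[i:(i + 2), ]
      if (!all(w$is_tbssr)) next
      if (rules$rit_require_same_strand && length(unique(w$strand)) > 1) next
      o1 <- cds_overlap(w$start[1], w$end[1], w$start[2], w$end[2])
      o2 <- cds_overlap(w$start[2], w$end[2], w$start[3], w$end[3])
      if (o1 < rules$rit_overlap_range[1] || o1 > rules$rit_overlap_range[2])
        next
      if (o2 < rules$rit_overlap_range[1] || o2 > rules$rit_overlap_range[2])
        next
      span <- max(w$end) - min(w$start)
      if (span < rules$rit_span_range[1] || span > rules$rit_span_range[2])
        next
      strand <- w$strand[1]
      members <- if (strand == "-") rev(w$id) else w$id
      calls[[length(calls) + 1L]] <- tibble(
        type = "RIT", replicon = w$replicon[1], start = min(w$start),
        end = max(w$end), span = span, strand = strand,
        members = list(members), has_tnpC = NA, conflict = FALSE,
        diagnostics = list(list(overlap_ab = o1, overlap_bc = o2,
                                span = span)))
    }
  }
  if (!length(calls)) return(empty_calls())
  out <- bind_rows(calls)
  flag_conflicts(out)
}

flag_conflicts <- function(calls) {
  if (nrow(calls) < 2) return(calls)
  ids <- calls$members
  for (i in seq_len(nrow(calls) - 1)) {
    for (j in seq((i + 1), nrow(calls))) {
      if (length(intersect(ids[[i]], ids[[j]]))) {
        calls$conflict[c(i, j)] <- TRUE
      }
    }
  }
  calls
}

#' Detect Tn554-like tandems
#'
#' Calls adjacent TBSSR pairs where one product lies in `tn554_long_range`
#' (611-828 aa) and the other in `tn554_short_range` (~350 aa), co-oriented
#' (if required) with an intergenic gap of at most `tn554_max_gap` bp.  When
#' the next same-strand gene downstream (in transcription direction) within
#' `tn554_max_gap` is a non-TBSSR, it is attached as the putative TnpC.  The
#' long member's N-terminal extension estimate (`product_len - 350`) is
#' flagged in the diagnostics when it reaches `long_next_extension_min`.
#'
#' @inheritParams find_rit
#' @return Element-call tibble; `members` lists long TBSSR, short TBSSR and
#'   (when present) the TnpC gene.
#' @export
find_tn554_like <- function(features, rules = element_rules()) {
  check_sorted(features)
  calls <- list()
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  for (rep_df in split(features, features$replicon)) {
    n <- nrow(rep_df)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      w <- rep_df[i:(i + 1), ]
      if (!all(w$is_tbssr)) next
      long_first <- in_range(w$product_len[1], rules$tn554_long_range) &&
        in_range(w$product_len[2], rules$tn554_short_range)
      short_first <- in_range(w$product_len[2], rules$tn554_long_range) &&
        in_range(w$product_len[1], rules$tn554_short_range)
      if (!long_first && !short_first) next
      if (rules$tn554_require_same_strand && w$strand[1] != w$strand[2]) next
      gap <- cds_gap(w$end[1], w$start[2])
      if (gap > rules$tn554_max_gap) next
      strand <- w$strand[1]
      long_row <- if (long_first) 1L else 2L
      members <- c(w$id[long_row], w$id[setdiff(1:2, long_row)])
      # putative TnpC: next gene in transcription direction
      tnpc_idx <- if (strand == "+") i + 2L else i - 1L
      has_tnpc <- FALSE
      if (tnpc_idx >= 1 && tnpc_idx <= n) {
        cand <- rep_df[tnpc_idx, ]
        g <- if (strand == "+") cds_gap(w$end[2], cand$start)
             else cds_gap(cand$end, w$start[1])
        if (!cand$is_tbssr && cand$strand == strand &&
            g <= rules$tn554_max_gap) {
          has_tnpc <- TRUE
          members <- c(members, cand$id)
        }
      }
      n_ext <- w$product_len[long_row] - 350L
      calls[[length(calls) + 1L]] <- tibble(
        type = "Tn554_like", replicon = w$replicon[1],
        start = min(w$start), end = max(w$end),
        span = max(w$end) - min(w$start), strand = strand,
        members = list(members), has_tnpC = has_tnpc, conflict = FALSE,
        diagnostics = list(list(
          long_aa = w$product_len[long_row],
          short_aa = w$product_len[setdiff(1:2, long_row)],
          gap = gap, n_extension = n_ext,
          long_extension_flag = n_ext >= rules$long_next_extension_min)))
    }
  }
  if (!length(calls)) return(empty_calls())
  flag_conflicts(bind_rows(calls))
}

#' Detect BIM elements (TBSSR + conserved partner gene)
#'
#' Calls every TBSSR feature adjacent (gap at most `bim_partner_max_gap`)
#' to a non-TBSSR feature of the designated partner family.
#'
#' @inheritParams find_rit
#' @param partner_famint Family index of the conserved partner protein
#'   (configuration error when missing).
#' @export
find_bim <- function(features, partner_famint, rules = element_rules()) {
  if (missing(partner_famint) || is.null(partner_famint) ||
      is.na(partner_famint)) {
    abort("partner_famint must be set for BIM detection")
  }
  check_sorted(features)
  calls <- list()
  for (rep_df in split(features, features$replicon)) {
    n <- nrow(rep_df)
    tb <- which(rep_df$is_tbssr)
    for (i in tb) {
      for (j in c(i - 1L, i + 1L)) {
        if (j < 1 || j > n) next
        cand <- rep_df[j, ]
        if (cand$is_tbssr || is.na(cand$famint) ||
            cand$famint != partner_famint) next
        gap <- if (j > i) cds_gap(rep_df$end[i], cand$start)
               else cds_gap(cand$end, rep_df$start[i])
        if (gap > rules$bim_partner_max_gap) next
        calls[[length(calls) + 1L]] <- tibble(
          type = "BIM", replicon = cand$replicon,
          start = min(rep_df$start[i], cand$start),
          end = max(rep_df$end[i], cand$end),
          span = max(rep_df$end[i], cand$end) -
            min(rep_df$start[i], cand$start),
          strand = rep_df$strand[i],
          members = list(c(rep_df$id[i], cand$id)), has_tnpC = NA,
          conflict = FALSE, diagnostics = list(list(gap = gap)))
      }
    }
  }
  if (!length(calls)) return(empty_calls())
  flag_conflicts(bind_rows(calls))
}

#' Run all element detectors on a feature table
#'
#' @inheritParams find_rit
#' @param bim_partner_famint Partner family for [find_bim()]; BIM detection
#'   is skipped when `NULL`.
#' @export
detect_elements <- function(features, rules = element_rules(),
                            bim_partner_famint = NULL) {
  out <- bind_rows(find_rit(features, rules),
                   find_tn554_like(features, rules))
  if (!is.null(bim_partner_famint)) {
    out <- bind_rows(out, find_bim(features, bim_partner_famint, rules))
  }
  out
}

#' Re-validate element calls against the rules
#'
#' Asserts that each call's recorded diagnostics satisfy the rules it was
#' made under; used as a self-consistency check.
#'
#' @param calls Element-call tibble.
#' @param rules [element_rules()].
#' @return `TRUE` invisibly; error on an inconsistent call.
#' @export
validate_element_calls <- function(calls, rules = element_rules()) {
  for (k in seq_len(nrow(calls))) {
    d <- calls$diagnostics[[k]]
    ok <- switch(
      calls$type[k],
      RIT = all(c(d$overlap_ab, d$overlap_bc) >= rules$rit_overlap_range[1]) &&
        all(c(d$overlap_ab, d$overlap_bc) <= rules$rit_overlap_range[2]) &&
        d$span >= rules$rit_span_range[1] && d$span <= rules$rit_span_range[2],
      Tn554_like = d$long_aa >= rules$tn554_long_range[1] &&
        d$long_aa <= rules$tn554_long_range[2] &&
        d$short_aa >= rules$tn554_short_range[1] &&
        d$short_aa <= rules$tn554_short_range[2] &&
        d$gap <= rules$tn554_max_gap,
      BIM = d$gap <= rules$bim_partner_max_gap,
      FALSE)
    if (!ok) abort(sprintf("call %d (%s) fails its own rules", k,
                           calls$type[k]))
  }
  invisible(TRUE)
}

#' Mirror a feature table (reverse-complement coordinates)
#'
#' Flips coordinates to `length - end` / `length - start`, inverts strands
#' and re-sorts; used to assert strand-mirror symmetry of the detectors.
#'
#' @param features Gene feature tibble.
#' @param replicon_length Length of the replicon in bp.
#' @export
mirror_features <- function(features, replicon_length) {
  features |>
    mutate(new_start = replicon_length - .data$end,
           new_end = replicon_length - .data$start,
           strand = ifelse(.data$strand == "+", "-", "+")) |>
    mutate(start = .data$new_start, end = .data$new_end) |>
    select(-"new_start", -"new_end") |>
    arrange(.data$replicon, .data$start, .data$end)
}
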
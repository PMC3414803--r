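# All-vs-all local alignment, E-values and the -log10(E) similarity graph.

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment with affine gaps under a [scoring_scheme()].
#' The traceback is deterministic: among equally scoring moves the diagonal
#' is preferred, then the vertical (gap in `b`), then the horizontal.
#'
#' @param a,b Protein sequences (strings).  Residues outside the 20-letter
#'   alphabet score 0 against everything.
#' @param scoring A [scoring_scheme()].
#' @return A list with `raw_score`, `identity` (matches / alignment columns,
#'   0 for an empty alignment), `aligned_ranges` (0-based half-open
#'   `c(q_start, q_end, s_start, s_end)`), and the alignment tallies
#'   `matches`, `mismatches`, `gapopens`, `gaps`, `aln_len`.
#' @examples
#' sw_align("ACDE", "ACDE")$raw_score  # 24 under BLOSUM62
#' @export
sw_align <- function(a, b, scoring = scoring_scheme()) {
  validate_protein_seq(a, "a")
  validate_protein_seq(b, "b")
  res <- sw_traceback_cpp(encode_seq(a), encode_seq(b),
                          scoring$substitution_matrix,
                          scoring$gap_open, scoring$gap_extend)
  identity <- if (res$aln_len > 0) res$matches / res$aln_len else 0
  list(raw_score = res$score,
       identity = identity,
       aligned_ranges = c(q_start = res$q_start, q_end = res$q_end,
                          s_start = res$s_start, s_end = res$s_end),
       matches = res$matches, mismatches = res$mismatches,
       gapopens = res$gapopens, gaps = res$gaps, aln_len = res$aln_len)
}

#' Global-scale identity of two sequences from their local alignment
#'
#' Matches in the optimal local alignment divided by the length of the
#' shorter sequence.  Unrelated sequences share only a short local core, so
#' this estimate stays near zero for them while tracking the substitution
#' rate for genuinely homologous pairs.
#'
#' @inheritParams sw_align
#' @return A fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, scoring = scoring_scheme()) {
  res <- sw_align(a, b, scoring)
  res$matches / min(nchar(a), nchar(b))
}

#' Karlin-Altschul E-value of a raw local alignment score
#'
#' `bit = (lambda * raw_score - ln K) / ln 2`; `E = m * n * 2^-bit` where `m`
#' is the query length and `n` the database size in residues.  E-values are
#' floored at 1e-200.
#'
#' @param raw_score Non-negative integer score(s).
#' @param query_len Query length in residues.
#' @param database_size Total database residues.
#' @param scoring A [scoring_scheme()] supplying lambda and K.
#' @return E-value(s), vectorised over `raw_score`.
#' @export
evalue <- function(raw_score, query_len, database_size,
                   scoring = scoring_scheme()) {
  if (any(raw_score < 0)) abort("raw_score must be >= 0")
  if (query_len <= 0 || database_size <= 0) abort("lengths must be positive")
  bit <- (scoring$lambda * raw_score - log(scoring$K)) / log(2)
  pmax(query_len * database_size * 2^(-bit), 1e-200)
}

#' Bit score of a raw alignment score
#' @inheritParams evalue
#' @export
bit_score <- function(raw_score, scoring = scoring_scheme()) {
  (scoring$lambda * raw_score - log(scoring$K)) / log(2)
}

#' All-vs-all similarity search
#'
#' Aligns every ordered pair of distinct proteins (each sequence queries the
#' whole set, as in a self-vs-self search), computes E-values against the
#' total residue count of the set, and keeps hits with `E <= e_cutoff`.
#' Self-hits are excluded.
#'
#' @param proteins Tibble with columns `id` (unique) and `sequence`.
#' @param scoring A [scoring_scheme()].
#' @param e_cutoff E-value cutoff (default 0.01).
#' @return Tibble of hits: `query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `e_value`, `identity`, and 0-based half-open
#'   `q_start`, `q_end`, `s_start`, `s_end`.  Carries the database size in
#'   attribute `database_size`.
#' @export
all_vs_all <- function(proteins, scoring = scoring_scheme(),
                       e_cutoff = 0.01) {
  if (anyDuplicated(proteins$id)) abort("protein ids must be unique")
  n <- nrow(proteins)
  db <- sum(nchar(proteins$sequence))
  empty <- tibble(query_id = character(), subject_id = character(),
                  raw_score = integer(), bit_score = double(),
                  e_value = double(), identity = double(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer())
  attr(empty, "database_size") <- db
  if (n < 2) return(empty)

  enc <- lapply(proteins$sequence, encode_seq)
  scores <- sw_scores_all_cpp(enc, scoring$substitution_matrix,
                              scoring$gap_open, scoring$gap_extend)
  lens <- nchar(proteins$sequence)
  # E depends on the query length, so evaluate both directions of each pair.
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      s <- scores[i, j]
      e_ij <- evalue(s, lens[i], db, scoring)
      e_ji <- evalue(s, lens[j], db, scoring)
      if (min(e_ij, e_ji) > e_cutoff) next
      tb <- sw_traceback_cpp(enc[[i]], enc[[j]], scoring$substitution_matrix,
                             scoring$gap_open, scoring$gap_extend)
      ident <- if (tb$aln_len > 0) tb$matches / tb$aln_len else 0
      if (e_ij <= e_cutoff) {
        rows[[length(rows) + 1L]] <- tibble(
          query_id = proteins$id[i], subject_id = proteins$id[j],
          raw_score = s, bit_score = bit_score(s, scoring), e_value = e_ij,
          identity = ident, q_start = tb$q_start, q_end = tb$q_end,
          s_start = tb$s_start, s_end = tb$s_end)
      }
      if (e_ji <= e_cutoff) {
        rows[[length(rows) + 1L]] <- tibble(
          query_id = proteins$id[j], subject_id = proteins$id[i],
          raw_score = s, bit_score = bit_score(s, scoring), e_value = e_ji,
          identity = ident, q_start = tb$s_start, q_end = tb$s_end,
          s_start = tb$q_start, s_end = tb$q_end)
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else empty
  attr(out, "database_size") <- db
  out
}

#' Build the -log10(E) similarity graph from hits
#'
#' Edge weight is `min(-log10(E), weight_cap)`; the two directions of a pair
#' are merged by taking the maximum weight (i.e. the smaller E-value).
#' Isolated proteins are retained as nodes when `nodes` is supplied.
#'
#' @param hits Hit tibble as from [all_vs_all()] or [read_hits_blasttab()];
#'   needs `query_id`, `subject_id`, `e_value`.
#' @param weight_cap Weight assigned to vanishing E-values (default 200).
#' @param nodes Optional character vector of all node ids (to keep proteins
#'   with no hits in the graph).
#' @param e_cutoff Cutoff recorded on the graph (hits are assumed filtered).
#' @param database_size Total database residues (recorded on the graph).
#' @return An object of class `similarity_graph`: list with `nodes`,
#'   `edges` (tibble `from`, `to`, `weight`, with `from < to` in node order),
#'   `weight_cap`, `e_cutoff`, `database_size`.
#' @export
build_graph <- function(hits, weight_cap = 200, nodes = NULL,
                        e_cutoff = 0.01, database_size = NA_integer_) {
  if (nrow(hits) > 0 && any(hits$e_value <= 0)) {
    abort("E-values must be positive")
  }
  node_ids <- sort(unique(c(nodes, hits$query_id, hits$subject_id)))
  nonself <- filter(hits, .data$query_id != .data$subject_id)
  if (nrow(nonself) == 0) {
    edges <- tibble(from = character(), to = character(), weight = double())
    if (is.na(database_size)) {
      database_size <- attr(hits, "database_size") %||% NA_integer_
    }
    return(structure(list(nodes = node_ids, edges = edges,
                          weight_cap = weight_cap, e_cutoff = e_cutoff,
                          database_size = database_size),
                     class = "similarity_graph"))
  }
  edges <- nonself |>
    mutate(w = pmin(-log10(.data$e_value), weight_cap),
           from = pmin(.data$query_id, .data$subject_id),
           to = pmax(.data$query_id, .data$subject_id)) |>
    group_by(.data$from, .data$to) |>
    summarise(weight = max(.data$w), .groups = "drop") |>
    arrange(.data$from, .data$to)
  if (is.na(database_size)) {
    database_size <- attr(hits, "database_size") %||% NA_integer_
  }
  structure(list(nodes = node_ids, edges = edges, weight_cap = weight_cap,
                 e_cutoff = e_cutoff, database_size = database_size),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("<similarity_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (weight cap ", x$weight_cap, ")\n", sep = "")
  invisible(x)
}

# Dense symmetric weight matrix of a similarity graph, node order preserved.
graph_matrix <- function(graph) {
  n <- length(graph$nodes)
  m <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    m[cbind(i, j)] <- graph$edges$weight
    m[cbind(j, i)] <- graph$edges$weight
  }
  m
}
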
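# Per-family multiple alignment: UPGMA guide tree from similarity-graph
# weights, progressive profile-profile merging with affine gaps.

#' UPGMA guide tree for a family
#'
#' Distances are `1 - w(i, j) / max(w)` over the family's similarity-graph
#' edges (missing edge -> distance 1); the tree is average-linkage
#' (`stats::hclust(method = "average")`).  Members are sorted by id first so
#' ties resolve deterministically.
#'
#' @param members Tibble with columns `id` and `sequence` (>= 2 rows).
#' @param graph A [build_graph()] similarity graph (may be `NULL`: all
#'   distances become 1).
#' @return An `hclust` object whose labels are the member ids.
#' @export
guide_tree <- function(members, graph = NULL) {
  ids <- sort(members$id)
  k <- length(ids)
  if (k < 2) abort("guide_tree needs at least 2 members")
  d <- matrix(1, k, k, dimnames = list(ids, ids))
  diag(d) <- 0
  if (!is.null(graph) && nrow(graph$edges)) {
    e <- graph$edges |>
      filter(.data$from %in% ids, .data$to %in% ids)
    if (nrow(e)) {
      w <- e$weight / max(e$weight)
      i <- match(e$from, ids)
      j <- match(e$to, ids)
      d[cbind(i, j)] <- 1 - w
      d[cbind(j, i)] <- 1 - w
    }
  }
  hclust(as.dist(d), method = "average")
}

# A profile: list(rows = named character vector of gapped strings).
profile_counts <- function(rows) {
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  nc <- ncol(chars)
  counts <- matrix(0, 21L, nc, dimnames = list(AA21, NULL))
  for (a in AA21) counts[a, ] <- colSums(chars == a)
  counts
}

merge_profiles <- function(rows1, rows2, scoring) {
  f1 <- profile_counts(rows1) / length(rows1)
  f2 <- profile_counts(rows2) / length(rows2)
  S <- scoring$substitution_matrix
  C <- t(f1) %*% S %*% f2   # mean-of-pairs column score; gaps contribute 0
  path <- nw_profile_path_cpp(C, scoring$gap_open, scoring$gap_extend)
  expand <- function(rows, cols) {
    chars <- strsplit(rows, "", fixed = TRUE)
    vapply(chars, function(ch) {
      out <- rep("-", length(cols))
      out[cols > 0] <- ch[cols[cols > 0]]
      paste(out, collapse = "")
    }, character(1))
  }
  c(expand(rows1, path$a_cols), expand(rows2, path$b_cols))
}

#' Progressive multiple alignment of a family
#'
#' Merges sequences bottom-up along the guide tree with global
#' profile-profile alignment (mean-of-pairs substitution scores, affine
#' gaps).  De-gapping any output row reproduces the corresponding input
#' sequence exactly.
#'
#' @param members Tibble with columns `id` and `sequence`.
#' @param tree Guide tree from [guide_tree()]; computed from `graph` when
#'   `NULL`.
#' @param scoring A [scoring_scheme()].
#' @param graph Optional similarity graph used when `tree` is `NULL`.
#' @param family_index Recorded on the result.
#' @return An object of class `msa`: list with `family_index`, `rows`
#'   (named character vector of equal-length gapped strings), `n_columns`.
#' @export
progressive_msa <- function(members, tree = NULL, scoring = scoring_scheme(),
                            graph = NULL, family_index = NA_integer_) {
  bad <- !grepl("^[A-Za-z]+$", members$sequence)
  if (any(bad)) abort("sequences must be plain residue strings")
  seqs <- setNames(toupper(members$sequence), members$id)
  if (length(seqs) == 1) {
    return(structure(list(family_index = family_index, rows = seqs,
                          n_columns = nchar(seqs[[1]])), class = "msa"))
  }
  if (is.null(tree)) tree <- guide_tree(members, graph)
  labs <- tree$labels
  node_rows <- vector("list", nrow(tree$merge))
  get_rows <- function(k) {
    if (k < 0) seqs[labs[-k]] else node_rows[[k]]
  }
  for (step in seq_len(nrow(tree$merge))) {
    a <- get_rows(tree$merge[step, 1])
    b <- get_rows(tree$merge[step, 2])
    node_rows[[step]] <- merge_profiles(a, b, scoring)
  }
  rows <- node_rows[[nrow(tree$merge)]]
  rows <- rows[order(match(names(rows), sort(members$id)))]
  structure(list(family_index = family_index, rows = rows,
                 n_columns = nchar(rows[[1]])), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> family ", x$family_index, ": ", length(x$rows), " rows x ",
      x$n_columns, " columns\n", sep = "")
  invisible(x)
}

#' Per-column conservation profile of an alignment
#'
#' The consensus residue and its fraction are computed over non-gap rows
#' only; the gap fraction is over all rows.  An all-gap column has consensus
#' `NA`, consensus fraction 0 and gap fraction 1.
#'
#' @param msa An [progressive_msa()] result (or any `msa` object).
#' @return Tibble with `column` (1-based), `consensus`, `consensus_frac`,
#'   `gap_frac`.
#' @export
column_conservation <- function(msa) {
  chars <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  n <- nrow(chars)
  per_col <- lapply(seq_len(ncol(chars)), function(j) {
    col <- chars[, j]
    gaps <- col == "-"
    res <- col[!gaps]
    if (length(res) == 0) {
      return(list(consensus = NA_character_, consensus_frac = 0,
                  gap_frac = 1))
    }
    tab <- sort(table(res), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    list(consensus = sort(top)[1], consensus_frac = max(tab) / length(res),
         gap_frac = sum(gaps) / n)
  })
  tibble(column = seq_along(per_col),
         consensus = vapply(per_col, `[[`, character(1), "consensus"),
         consensus_frac = vapply(per_col, `[[`, numeric(1), "consensus_frac"),
         gap_frac = vapply(per_col, `[[`, numeric(1), "gap_frac"))
}

#' Map an alignment column to ungapped sequence positions
#'
#' @param msa An `msa` object.
#' @param column 1-based alignment column.
#' @return Named integer vector: for each row, the 0-based ungapped index
#'   of the residue in that column (`NA` where the row has a gap).
#' @export
column_to_positions <- function(msa, column) {
  chars <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  upos <- t(apply(chars != "-", 1, cumsum))
  out <- ifelse(chars[, column] == "-", NA_integer_,
                upos[, column] - 1L)
  setNames(as.integer(out), names(msa$rows))
}
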
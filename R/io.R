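# File-format plumbing.  Coordinates are 0-based half-open everywhere
# inside the package; 1-based inclusive coordinates appear only in the
# files themselves (BLAST tabular, GFF3).

#' Read a protein FASTA into a tibble
#'
#' The first whitespace-delimited token of each header is the protein id.
#'
#' @param path FASTA file.
#' @return Tibble with `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) abort("duplicate ids in FASTA")
  seqs <- unname(as.character(ss))
  tibble(id = ids, sequence = seqs, length = nchar(seqs))
}

#' Write sequences to FASTA
#'
#' @param proteins Tibble with `id` and `sequence` (a named character
#'   vector also works).
#' @param path Output file.
#' @param width Line width (default 60).
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  if (is.character(proteins)) {
    proteins <- tibble(id = names(proteins), sequence = unname(proteins))
  }
  ss <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read / write the per-protein metadata sidecar TSV
#'
#' Columns: `protein_id`, `mge_type`, `host`, `replicon`.
#'
#' @param path TSV file.
#' @export
read_metadata_tsv <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("protein_id", "mge_type", "host", "replicon")
  if (!all(need %in% names(md))) {
    abort(paste("metadata TSV must have columns:", paste(need, collapse = ", ")))
  }
  md
}

#' @rdname read_metadata_tsv
#' @param proteins Tibble with `id`, `mge_type`, `host`, `replicon`.
#' @export
write_metadata_tsv <- function(proteins, path) {
  proteins |>
    select(protein_id = "id", "mge_type", "host", "replicon") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Read a BLAST tabular (12-column) hit table
#'
#' Standard `qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore` columns; the file's 1-based inclusive
#' coordinates are converted to 0-based half-open.
#'
#' @param path Hit table file (no header).
#' @return Hit tibble compatible with [build_graph()].
#' @export
read_hits_blasttab <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "e_value",
            "bit_score")
  h <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                       col_types = "ccdiiiiiiidd")
  if (any(is.na(h$e_value))) abort("malformed hit table: missing E-values")
  h |>
    mutate(identity = .data$pident / 100,
           q_start = .data$qstart - 1L, q_end = .data$qend,
           s_start = .data$sstart - 1L, s_end = .data$send) |>
    select("query_id", "subject_id", "identity", "length", "mismatch",
           "gapopen", "q_start", "q_end", "s_start", "s_end", "e_value",
           "bit_score")
}

#' Write hits as BLAST tabular (12 columns)
#'
#' @param hits Hit tibble from [all_vs_all()].
#' @param path Output file.
#' @export
write_hits_blasttab <- function(hits, path) {
  out <- hits |>
    mutate(pident = sprintf("%.2f", 100 * .data$identity),
           length = .data$q_end - .data$q_start,
           mismatch = if ("mismatches" %in% names(hits)) .data$mismatches
                      else NA_integer_,
           gapopen = if ("gapopens" %in% names(hits)) .data$gapopens
                     else 0L,
           qstart = .data$q_start + 1L, qend = .data$q_end,
           sstart = .data$s_start + 1L, send = .data$s_end,
           evalue = signif(.data$e_value, 3),
           bitscore = sprintf("%.1f", .data$bit_score)) |>
    select("query_id", "subject_id", "pident", "length", "mismatch",
           "gapopen", "qstart", "qend", "sstart", "send", "evalue",
           "bitscore")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read / write a 3-column ABC edge list
#'
#' `id1 TAB id2 TAB weight`, the standard MCL input dialect.
#'
#' @param path Edge-list file.
#' @param nodes Optional full node set (isolated nodes are lost in the file
#'   format and can be restored here).
#' @param weight_cap,e_cutoff Recorded on the rebuilt graph.
#' @export
read_abc <- function(path, nodes = NULL, weight_cap = 200, e_cutoff = 0.01) {
  e <- readr::read_tsv(path, col_names = c("from", "to", "weight"),
                       show_col_types = FALSE, col_types = "ccd")
  node_ids <- sort(unique(c(nodes, e$from, e$to)))
  edges <- e |>
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
    group_by(from = .data$a, to = .data$b) |>
    summarise(weight = max(.data$weight), .groups = "drop") |>
    arrange(.data$from, .data$to)
  structure(list(nodes = node_ids, edges = edges, weight_cap = weight_cap,
                 e_cutoff = e_cutoff, database_size = NA_integer_),
            class = "similarity_graph")
}

#' @rdname read_abc
#' @param graph A `similarity_graph`.
#' @export
write_abc <- function(graph, path) {
  readr::write_tsv(graph$edges, path, col_names = FALSE)
  invisible(path)
}

#' Write clusters in the native MCL line-per-cluster format
#'
#' @param partition A `famint_partition`.
#' @param path Output file (tab-separated member ids, one family per line,
#'   families in index order).
#' @export
write_mcl_clusters <- function(partition, path) {
  members <- partition_members(partition)
  writeLines(vapply(members, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' Write the protein-to-family assignment TSV
#' @param partition A `famint_partition`.
#' @param path Output file.
#' @export
write_partition_tsv <- function(partition, path) {
  readr::write_tsv(partition$assignment, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Keeps CDS features (all features when none are typed CDS), converts the
#' file's 1-based inclusive coordinates to 0-based half-open, and derives
#' `product_len` as `width/3 - 1` aa unless a `product_len` attribute is
#' present.  A feature is a TBSSR when its ID is in `tbssr_ids`, its
#' `is_tbssr` attribute is true, or its `product` attribute matches
#' `tbssr_pattern`.
#'
#' @param path GFF3 file.
#' @param tbssr_ids Optional character vector of TBSSR feature IDs.
#' @param tbssr_pattern Regex on the `product` attribute (default
#'   `"recombinase|integrase|TBSSR"`, case-insensitive).
#' @return Feature tibble as used by [find_rit()] and friends.
#' @export
read_gff3 <- function(path, tbssr_ids = NULL,
                      tbssr_pattern = "recombinase|integrase|TBSSR") {
  g <- as.data.frame(rtracklayer::readGFF(path))
  if (any(g$type == "CDS")) g <- g[g$type == "CDS", ]
  att <- function(name, default) {
    if (name %in% names(g)) g[[name]] else rep(default, nrow(g))
  }
  id <- att("ID", NA_character_)
  if (anyNA(id)) id[is.na(id)] <- sprintf("feat%04d", which(is.na(id)))
  start0 <- as.integer(g$start) - 1L
  end0 <- as.integer(g$end)
  plen <- suppressWarnings(as.integer(att("product_len", NA)))
  plen[is.na(plen)] <- (end0 - start0)[is.na(plen)] %/% 3L - 1L
  is_tb <- tolower(as.character(att("is_tbssr", "false"))) %in%
    c("true", "1", "yes")
  prod <- as.character(att("product", ""))
  is_tb <- is_tb | grepl(tbssr_pattern, prod, ignore.case = TRUE)
  if (!is.null(tbssr_ids)) is_tb <- is_tb | id %in% tbssr_ids
  fam <- suppressWarnings(as.integer(att("famint", NA)))
  tibble(replicon = as.character(g$seqid), start = start0, end = end0,
         strand = as.character(g$strand), id = id, product_len = plen,
         is_tbssr = is_tb, famint = fam) |>
    arrange(.data$replicon, .data$start, .data$end)
}

#' Write gene features as GFF3
#'
#' @param features Feature tibble (internal 0-based half-open coordinates;
#'   written 1-based inclusive).
#' @param path Output file.
#' @param source Value for the source column.
#' @export
write_gff3 <- function(features, path, source = "famintr") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product_len=%d;is_tbssr=%s%s",
                     features$replicon, source, features$start + 1L,
                     features$end, features$strand, features$id,
                     features$product_len,
                     ifelse(features$is_tbssr, "true", "false"),
                     ifelse(is.na(features$famint), "",
                            sprintf(";famint=%d", features$famint))))
  writeLines(lines, path)
  invisible(path)
}

#' Write element calls as GFF3 plus a diagnostics TSV
#'
#' @param calls Element-call tibble.
#' @param gff_path,tsv_path Output files.
#' @export
write_element_calls <- function(calls, gff_path, tsv_path) {
  lines <- "##gff-version 3"
  if (nrow(calls)) {
    lines <- c(lines, sprintf(
      "%s\tfamintr\tmobile_genetic_element\t%d\t%d\t.\t%s\t.\tID=%s_%03d;element_type=%s;members=%s",
      calls$replicon, calls$start + 1L, calls$end, calls$strand,
      tolower(calls$type), seq_len(nrow(calls)), calls$type,
      vapply(calls$members, paste, character(1), collapse = ",")))
  }
  writeLines(lines, gff_path)
  flat <- calls |>
    mutate(members = vapply(.data$members, paste, character(1),
                            collapse = ","),
           diagnostics = vapply(.data$diagnostics, function(d) {
             paste(names(d), unlist(d), sep = "=", collapse = ";")
           }, character(1)))
  readr::write_tsv(flat, tsv_path)
  invisible(gff_path)
}

#' Write the inflation-sweep report TSV
#' @param sweep A `famint_sweep`.
#' @param path Output file.
#' @export
write_sweep_tsv <- function(sweep, path) {
  readr::write_tsv(as_tibble(sweep)[, c("inflation", "n_families",
                                        "n_singletons", "iccc",
                                        "converged")], path)
  invisible(path)
}
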
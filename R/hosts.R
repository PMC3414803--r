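# Host-host network from shared families: genus grouping, weighted edges,
# components and hub removal.

host_genus <- function(host) {
  toks <- strsplit(trimws(host), "\\s+")
  vapply(toks, function(t) {
    t <- t[t != "Candidatus"]
    if (length(t) == 0) NA_character_ else t[1]
  }, character(1))
}

#' Group host strains into network nodes
#'
#' Hosts are grouped at the genus level (first whitespace token, skipping a
#' leading "Candidatus"); a genus with a single representative keeps its
#' full species/strain label.
#'
#' @param proteins Tibble with a `host` column (or a character vector of
#'   host strings).
#' @return Tibble with `label` (node name), `genus`, `members` (list column
#'   of distinct host strings), `n_members`.
#' @export
group_hosts <- function(proteins) {
  hosts <- if (is.character(proteins)) proteins else proteins$host
  hosts <- unique(hosts[!is.na(hosts) & nzchar(hosts)])
  if (length(hosts) == 0) {
    return(tibble(label = character(), genus = character(),
                  members = list(), n_members = integer()))
  }
  genus <- host_genus(hosts)
  bad <- is.na(genus)
  if (any(bad)) {
    warn(paste("unparseable host string(s):",
               paste(hosts[bad], collapse = ", ")))
    genus[bad] <- hosts[bad]
  }
  tibble(host = hosts, genus = genus) |>
    group_by(.data$genus) |>
    summarise(members = list(sort(.data$host)),
              n_members = n(), .groups = "drop") |>
    mutate(label = ifelse(.data$n_members > 1, .data$genus,
                          vapply(.data$members, `[`, character(1), 1))) |>
    select("label", "genus", "members", "n_members") |>
    arrange(.data$label)
}

#' Host-host graph weighted by shared families
#'
#' A family is present in a host node if any member of the family has a
#' host mapped to that node; the edge weight between two nodes is the
#' number of families of size >= `min_family_size` present in both.
#' Zero-share pairs get no edge.
#'
#' @param partition A `famint_partition`.
#' @param proteins Tibble with `id` and `host`.
#' @param nodes Optional [group_hosts()] table (computed when `NULL`).
#' @param min_family_size Smallest family that can contribute an edge
#'   (default 2; singleton families cannot be shared).
#' @return An object of class `host_graph`: list with `nodes` (tibble),
#'   `edges` (tibble `from`, `to`, `weight`), `incidence` (tibble `famint`,
#'   `label`), `min_family_size`.
#' @export
shared_family_graph <- function(partition, proteins, nodes = NULL,
                                min_family_size = 2L) {
  if (is.null(nodes)) nodes <- group_hosts(proteins)
  host_to_label <- nodes |>
    tidyr::unnest_longer("members", values_to = "host") |>
    select("host", "label")
  sizes <- tibble(famint = seq_along(partition$family_sizes) - 1L,
                  size = partition$family_sizes)
  incidence <- partition$assignment |>
    left_join(proteins |> select("id", "host"),
              by = c(protein_id = "id")) |>
    left_join(host_to_label, by = "host") |>
    left_join(sizes, by = "famint") |>
    filter(.data$size >= min_family_size, !is.na(.data$label)) |>
    distinct(.data$famint, .data$label)
  edges <- incidence |>
    inner_join(incidence, by = "famint", relationship = "many-to-many") |>
    filter(.data$label.x < .data$label.y) |>
    count(from = .data$label.x, to = .data$label.y, name = "weight") |>
    arrange(.data$from, .data$to)
  structure(list(nodes = nodes, edges = edges, incidence = incidence,
                 min_family_size = as.integer(min_family_size)),
            class = "host_graph")
}

#' @export
print.host_graph <- function(x, ...) {
  cat("<host_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges; ", length(host_components(x)), " components\n", sep = "")
  invisible(x)
}

host_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("from", "to", "weight")], directed = FALSE,
    vertices = data.frame(name = graph$nodes$label))
}

#' Connected components of a host graph
#'
#' @param graph A [shared_family_graph()] result.
#' @return List of character vectors (node labels), ordered by decreasing
#'   size then smallest label.
#' @export
host_components <- function(graph) {
  comp <- igraph::components(host_igraph(graph))
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(sets, sort)
  ord <- order(-lengths(sets), vapply(sets, `[`, character(1), 1))
  unname(sets[ord])
}

#' Effect of removing hub nodes on the component structure
#'
#' @param graph A [shared_family_graph()] result.
#' @param remove Character vector of node labels to drop (error when a
#'   label does not exist).
#' @return List with `components_before`, `components_after` (both lists of
#'   label sets), and counts `n_before`, `n_after`.
#' @export
hub_impact <- function(graph, remove) {
  missing_lab <- setdiff(remove, graph$nodes$label)
  if (length(missing_lab)) {
    abort(paste("unknown node label(s):", paste(missing_lab, collapse = ", ")))
  }
  before <- host_components(graph)
  sub <- graph
  sub$nodes <- filter(graph$nodes, !.data$label %in% remove)
  sub$edges <- filter(graph$edges, !.data$from %in% remove,
                      !.data$to %in% remove)
  after <- host_components(sub)
  list(components_before = before, components_after = after,
       n_before = length(before), n_after = length(after))
}
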
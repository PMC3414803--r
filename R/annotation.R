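# Per-family MGE composition, specificity classification and the
# family-table report.

#' Rules for family annotation
#'
#' @param min_family_size Families below this size are classed `"small"`
#'   (default 4).
#' @param purity_threshold Minimum fraction of one (merged) MGE class for a
#'   family to be type-specific (default 0.9; must exceed 0.5).
#' @param merge_phage_prophage Treat phage and prophage as one
#'   `"(pro)phage"` class for specificity (default `TRUE`).
#' @param defective_max_len Members strictly shorter than this (aa) are
#'   flagged as likely defective (default 200).
#' @export
annotation_rules <- function(min_family_size = 4L, purity_threshold = 0.9,
                             merge_phage_prophage = TRUE,
                             defective_max_len = 200L) {
  if (!(purity_threshold > 0.5 && purity_threshold <= 1)) {
    abort("purity_threshold must be in (0.5, 1]")
  }
  list(min_family_size = as.integer(min_family_size),
       purity_threshold = purity_threshold,
       merge_phage_prophage = merge_phage_prophage,
       defective_max_len = as.integer(defective_max_len))
}

merged_class <- function(mge_type, rules) {
  if (rules$merge_phage_prophage) {
    ifelse(mge_type %in% c("phage", "prophage"), "(pro)phage", mge_type)
  } else {
    mge_type
  }
}

#' Per-family MGE-type composition
#'
#' @param partition A `famint_partition`.
#' @param proteins Tibble with `id` and `mge_type` covering every assigned
#'   id (error otherwise).
#' @return Tibble `famint`, `mge_type`, `n` (raw counts, one row per type
#'   present).
#' @export
family_composition <- function(partition, proteins) {
  missing_ids <- setdiff(partition$assignment$protein_id, proteins$id)
  if (length(missing_ids)) {
    abort(paste("unknown protein id(s):",
                paste(head(missing_ids, 5), collapse = ", ")))
  }
  partition$assignment |>
    left_join(proteins |> select("id", "mge_type"),
              by = c(protein_id = "id")) |>
    count(.data$famint, .data$mge_type, name = "n") |>
    arrange(.data$famint, .data$mge_type)
}

#' Classify the MGE-type specificity of one family
#'
#' A family below `min_family_size` is `"small"`; otherwise it is
#' `"specific:<class>"` when the largest merged-class fraction reaches
#' `purity_threshold`, else `"mixed"`.
#'
#' @param composition Named integer vector of per-type counts for one
#'   family (e.g. `c(phage = 16, prophage = 36)`).
#' @param rules [annotation_rules()].
#' @return The specificity label (string).
#' @export
classify_specificity <- function(composition, rules = annotation_rules()) {
  if (length(composition) == 0) abort("composition is empty")
  size <- sum(composition)
  if (size < rules$min_family_size) return("small")
  merged <- tapply(composition, merged_class(names(composition), rules), sum)
  frac <- merged / size
  best <- which.max(frac)
  if (frac[best] >= rules$purity_threshold) {
    paste0("specific:", names(merged)[best])
  } else {
    "mixed"
  }
}

#' Flag likely-defective short family members
#'
#' @param members Tibble with `id` and `length` (aa).
#' @param rules [annotation_rules()].
#' @return Character vector of ids with `length < defective_max_len`
#'   (strict).
#' @export
flag_defective <- function(members, rules = annotation_rules()) {
  members$id[members$length < rules$defective_max_len]
}

#' Annotate every family of a partition
#'
#' Combines composition, specificity, motif labels and defective-member
#' flags into one per-family profile table.
#'
#' @param partition A `famint_partition`.
#' @param proteins Tibble with `id`, `mge_type`, `length`.
#' @param motifs Optional [family_motifs()] table supplying motif labels.
#' @param rules [annotation_rules()].
#' @return Tibble with `famint`, `size`, `specificity`, `motif_label`,
#'   `purity` (largest merged-class fraction), `composition` (list column
#'   of named counts), `defective_ids` (list column).
#' @export
annotate_families <- function(partition, proteins, motifs = NULL,
                              rules = annotation_rules()) {
  comp <- family_composition(partition, proteins)
  members <- partition_members(partition)
  rows <- lapply(names(members), function(f) {
    fi <- as.integer(f)
    cc <- comp |> filter(.data$famint == fi)
    counts <- setNames(cc$n, cc$mge_type)
    merged <- tapply(counts, merged_class(names(counts), rules), sum)
    mem <- proteins[match(members[[f]], proteins$id), ]
    label <- if (!is.null(motifs) && fi %in% motifs$famint) {
      motifs$label[match(fi, motifs$famint)]
    } else {
      NA_character_
    }
    tibble(famint = fi, size = sum(counts),
           specificity = classify_specificity(counts, rules),
           motif_label = label,
           purity = max(merged) / sum(counts),
           composition = list(counts),
           defective_ids = list(flag_defective(mem, rules)))
  })
  bind_rows(rows)
}

#' Family-table report with size-class summary and headline percentages
#'
#' One row per family of size >= `min_family_size`, plus a size-class
#' summary (3-member families, 2-member families, singletons) and two
#' headline statistics: `pct_specific` counts a protein as MGE-type
#' specific iff its family has size >= `min_family_size` and is classified
#' specific; `pct_specific_any` relaxes the size condition (small pure
#' families, including singletons, count as specific).
#'
#' @param profiles [annotate_families()] output.
#' @param partition The `famint_partition` the profiles came from.
#' @param rules [annotation_rules()].
#' @return An object of class `famint_report`: list with `families`
#'   (tibble), `size_summary` (tibble `size_class`, `n_families`),
#'   `pct_specific`, `pct_specific_any`, `n_proteins`.
#' @export
family_report <- function(profiles, partition, rules = annotation_rules()) {
  n_total <- nrow(partition$assignment)
  fam <- profiles |>
    filter(.data$size >= rules$min_family_size) |>
    arrange(.data$famint)
  small <- profiles |> filter(.data$size < rules$min_family_size)
  size_summary <- tibble(
    size_class = c("3 members", "2 members", "singletons"),
    n_families = c(sum(small$size == 3L), sum(small$size == 2L),
                   sum(small$size == 1L)))
  specific_large <- sum(fam$size[startsWith(fam$specificity, "specific")])
  pure_any <- profiles |>
    filter(.data$purity >= rules$purity_threshold)
  structure(list(
    families = fam |> select(-"composition", -"defective_ids") |>
      bind_cols(composition_wide(fam)),
    size_summary = size_summary,
    pct_specific = 100 * specific_large / n_total,
    pct_specific_any = 100 * sum(pure_any$size) / n_total,
    n_proteins = n_total), class = "famint_report")
}

composition_wide <- function(profiles) {
  types <- c(MGE_TYPES, "unknown")
  m <- matrix(0L, nrow(profiles), length(types),
              dimnames = list(NULL, paste0("n_", types)))
  for (k in seq_len(nrow(profiles))) {
    cc <- profiles$composition[[k]]
    m[k, paste0("n_", names(cc))] <- as.integer(cc)
  }
  as_tibble(m[, colSums(m) > 0 | colnames(m) %in%
                c("n_phage", "n_prophage", "n_plasmid", "n_GI"),
              drop = FALSE])
}

#' @export
print.famint_report <- function(x, ...) {
  cat("<famint_report> ", x$n_proteins, " proteins; ",
      nrow(x$families), " families above the size threshold\n", sep = "")
  cat(sprintf("  %% in MGE-type-specific families: %.1f (size-restricted), %.1f (any size)\n",
              x$pct_specific, x$pct_specific_any))
  print(x$size_summary)
  invisible(x)
}

#' Reference family compositions bundled with the package
#'
#' Reads the bundled reference table of family sizes and per-MGE-type
#' member counts for a published curated TBSSR corpus (families of four or
#' more members, with the manually assigned type and catalytic-motif
#' labels).  Used to check the specificity classifier against manual
#' labels.
#'
#' @return Tibble with `famint`, `mge_type_label`, `n_prot`, `n_gi`,
#'   `n_phage`, `n_prophage`, `n_plasmid`, `motif_label`.
#' @export
reference_family_table <- function() {
  path <- system.file("extdata", "tbssr_reference_families.tsv",
                      package = "famintr")
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}

#' Composition vector of one reference family
#' @param famint Family index in [reference_family_table()].
#' @export
reference_composition <- function(famint) {
  tab <- reference_family_table()
  row <- tab[tab$famint == famint, ]
  if (nrow(row) != 1) abort(paste("no reference family", famint))
  counts <- c(GI = row$n_gi, phage = row$n_phage, prophage = row$n_prophage,
              plasmid = row$n_plasmid)
  counts[counts > 0]
}
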
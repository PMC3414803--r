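# Catalytic-motif detection: a conserved C-terminal tyrosine with a
# conserved arginine ~30 residues upstream, read from alignment columns.

#' Options for the catalytic-motif scan
#'
#' @param conservation_min Minimum consensus fraction for a column to count
#'   as conserved (default 0.9).
#' @param gap_max Maximum gap fraction for a conserved column (default 0.2).
#' @param spacing_range Allowed per-row ungapped R-to-Y spacing, summarised
#'   by the median (default 20-40 residues, "around 30").
#' @param c_terminal_window Fraction of alignment columns, from the right,
#'   in which the Y is sought (default 0.35).
#' @param min_rows Families with fewer rows are not called (default 4).
#' @export
motif_options <- function(conservation_min = 0.9, gap_max = 0.2,
                          spacing_range = c(20L, 40L),
                          c_terminal_window = 0.35, min_rows = 4L) {
  if (!(conservation_min > 0 && conservation_min <= 1)) {
    abort("conservation_min must be in (0, 1]")
  }
  if (spacing_range[1] > spacing_range[2]) abort("spacing_range is not ordered")
  list(conservation_min = conservation_min, gap_max = gap_max,
       spacing_range = as.integer(spacing_range),
       c_terminal_window = c_terminal_window, min_rows = as.integer(min_rows))
}

#' Find the catalytic R...Y motif in a family alignment
#'
#' Scans conserved tyrosine columns in the C-terminal window, rightmost
#' first; for each, scans upstream conserved arginine columns (nearest
#' first) whose per-row ungapped spacing to the Y has a median inside
#' `spacing_range`.  The first satisfying pair wins.  The motif label is
#' `"R"`, followed by the consensus residues of the run of conserved columns
#' immediately after the R column (at most 4), then `"-Y"` -- e.g. `"RH-Y"`.
#' Families with no qualifying pair are labelled `"no obvious one"`.
#'
#' @param msa An `msa` object.
#' @param opts [motif_options()].
#' @return An object of class `motif_call`: list with `found`, `y_column`,
#'   `r_column`, `median_spacing`, `label`, `y_conservation`,
#'   `r_conservation`, `n_rows` and (when not found) `reason`.
#' @export
find_catalytic_motif <- function(msa, opts = motif_options()) {
  n_rows <- length(msa$rows)
  not_found <- function(reason) {
    structure(list(found = FALSE, y_column = NA_integer_,
                   r_column = NA_integer_, median_spacing = NA_real_,
                   label = "no obvious one", y_conservation = NA_real_,
                   r_conservation = NA_real_, n_rows = n_rows,
                   reason = reason), class = "motif_call")
  }
  if (n_rows < opts$min_rows) return(not_found("too few rows"))

  prof <- column_conservation(msa)
  conserved <- prof$consensus_frac >= opts$conservation_min &
    prof$gap_frac <= opts$gap_max
  nc <- nrow(prof)
  window_start <- nc - ceiling(nc * opts$c_terminal_window) + 1L
  y_cols <- which(conserved & prof$consensus == "Y" &
                    prof$column >= window_start)
  if (length(y_cols) == 0) return(not_found("no conserved Y in window"))

  # Per-row ungapped residue index at every column.
  chars <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  upos <- t(apply(chars != "-", 1, cumsum))

  for (y in rev(y_cols)) {
    r_cols <- which(conserved[seq_len(y - 1)] &
                      prof$consensus[seq_len(y - 1)] == "R")
    for (r in rev(r_cols)) {  # nearest R first
      ok <- chars[, y] != "-" & chars[, r] != "-"
      if (!any(ok)) next
      spacing <- median(upos[ok, y] - upos[ok, r])
      if (spacing >= opts$spacing_range[1] &&
          spacing <= opts$spacing_range[2]) {
        run <- character(0)
        j <- r + 1L
        while (j < y && length(run) < 4 && conserved[j]) {
          run <- c(run, prof$consensus[j])
          j <- j + 1L
        }
        return(structure(list(
          found = TRUE, y_column = y, r_column = r,
          median_spacing = spacing,
          label = paste0("R", paste(run, collapse = ""), "-Y"),
          y_conservation = prof$consensus_frac[y],
          r_conservation = prof$consensus_frac[r],
          n_rows = n_rows, reason = NA_character_), class = "motif_call"))
      }
    }
  }
  not_found("no R/Y pair at the expected spacing")
}

#' @export
print.motif_call <- function(x, ...) {
  if (x$found) {
    cat("<motif_call> ", x$label, " (Y col ", x$y_column, ", R col ",
        x$r_column, ", median spacing ", x$median_spacing, ")\n", sep = "")
  } else {
    cat("<motif_call> not found (", x$reason, ")\n", sep = "")
  }
  invisible(x)
}

#' Align and scan every family of a partition
#'
#' Convenience wrapper: builds the per-family MSA ([progressive_msa()]) and
#' motif call ([find_catalytic_motif()]) for every family with at least
#' `min_members` members.
#'
#' @param partition A `famint_partition`.
#' @param proteins Tibble with `id` and `sequence`.
#' @param graph Similarity graph used for the guide trees.
#' @param scoring A [scoring_scheme()].
#' @param opts [motif_options()].
#' @param min_members Smallest family to align (default 2).
#' @return Tibble with `famint`, `size`, `found`, `label`, `y_column`,
#'   `r_column`, `median_spacing`, `y_conservation`, `r_conservation`, and
#'   list columns `msa` and `motif`.
#' @export
family_motifs <- function(partition, proteins, graph = NULL,
                          scoring = scoring_scheme(),
                          opts = motif_options(), min_members = 2L) {
  members <- partition_members(partition)
  members <- members[lengths(members) >= min_members]
  rows <- lapply(names(members), function(f) {
    ids <- members[[f]]
    mem <- proteins[match(ids, proteins$id), c("id", "sequence")]
    aln <- progressive_msa(mem, scoring = scoring, graph = graph,
                           family_index = as.integer(f))
    call <- find_catalytic_motif(aln, opts)
    tibble(famint = as.integer(f), size = length(ids), found = call$found,
           label = call$label, y_column = call$y_column,
           r_column = call$r_column, median_spacing = call$median_spacing,
           y_conservation = call$y_conservation,
           r_conservation = call$r_conservation,
           msa = list(aln), motif = list(call))
  })
  bind_rows(rows)
}
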
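# Exact direct/inverted repeat scanning for element boundaries.

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  split(starts, kmers)
}

low_complexity <- function(s) {
  tab <- table(strsplit(s, "", fixed = TRUE)[[1]])
  length(tab) <= 2 || max(tab) / sum(tab) >= 0.8
}

#' Scan a sequence for direct and inverted exact repeats
#'
#' Finds maximal (non-extendable) exact repeats of length >= `min_len`
#' whose copies start within `max_window` bp of each other.  Inverted
#' repeats match the reverse complement.  Every seed inside a maximal
#' repeat extends to the same maximal pair, so each repeat is reported
#' once.  Repeats whose sequence is low-complexity (<= 2 distinct bases or
#' one base at >= 80%), e.g. within homopolymer runs, are flagged and, by
#' default, dropped.
#'
#' @param sequence Nucleotide string over A, C, G, T, N.
#' @param min_len Minimum repeat length (default 9).
#' @param max_window Maximum distance between the two copy starts (default
#'   600 bp).
#' @param drop_low_complexity Drop flagged repeats (default `TRUE`).
#' @return Tibble with `type` (`"direct"`/`"inverted"`), `pos1`, `pos2`
#'   (0-based starts of the two copies, `pos1 < pos2`), `length`,
#'   `low_complexity`.
#' @export
scan_repeats <- function(sequence, min_len = 9L, max_window = 600L,
                         drop_low_complexity = TRUE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) abort("sequence must be over A,C,G,T,N")
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cchars <- strsplit(chartr("ACGTN", "TGCAN", sequence), "",
                     fixed = TRUE)[[1]]
  rows <- list()
  seen <- new.env(hash = TRUE)
  note <- function(type, i, j, len) {
    key <- paste(type, i, j, len)
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    s <- substr(sequence, i, i + len - 1L)
    rows[[length(rows) + 1L]] <<- tibble(
      type = type, pos1 = i - 1L, pos2 = j - 1L, length = len,
      low_complexity = low_complexity(s))
  }

  pos_fwd <- kmer_positions(sequence, min_len)

  # Direct repeats: the same k-mer at two starts, extended both ways.
  for (pos in pos_fwd) {
    if (length(pos) < 2) next
    for (a in seq_len(length(pos) - 1)) {
      for (b in seq((a + 1), length(pos))) {
        i <- pos[a]; j <- pos[b]
        if (j - i > max_window) next
        len <- min_len
        while (i > 1 && chars[i - 1] == chars[j - 1]) {
          i <- i - 1L; j <- j - 1L; len <- len + 1L
        }
        while (j + len <= n && chars[i + len] == chars[j + len]) {
          len <- len + 1L
        }
        note("direct", i, j, len)
      }
    }
  }

  # Inverted repeats: a k-mer whose reverse complement occurs downstream.
  for (km in names(pos_fwd)) {
    rc_km <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", km), "",
                                fixed = TRUE)[[1]]), collapse = "")
    js <- pos_fwd[[rc_km]]
    if (is.null(js)) next
    for (i0 in pos_fwd[[km]]) {
      for (j0 in js) {
        i <- i0; j <- j0
        if (j <= i || j - i > max_window) next
        len <- min_len       # copy2 = [j, j+len) = revcomp(copy1)
        while (i > 1 && j + len <= n && chars[i - 1] == cchars[j + len]) {
          i <- i - 1L; len <- len + 1L
        }
        while (j > i + len && chars[i + len] == cchars[j - 1]) {
          j <- j - 1L; len <- len + 1L
        }
        note("inverted", i, j, len)
      }
    }
  }

  if (!length(rows)) {
    return(tibble(type = character(), pos1 = integer(), pos2 = integer(),
                  length = integer(), low_complexity = logical()))
  }
  out <- bind_rows(rows) |> distinct() |>
    arrange(.data$type, .data$pos1, .data$pos2)
  if (drop_low_complexity) out <- filter(out, !.data$low_complexity)
  out
}
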
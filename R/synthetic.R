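# Synthetic TBSSR corpora with planted ground truth: protein families with
# known membership, MGE-type and host labels, planted catalytic motifs, and
# annotated replicons carrying composite elements and rule-violating decoys.

MGE_TYPES <- c("phage", "prophage", "plasmid", "GI", "ICE", "RIT", "BIM")

default_hosts <- function() {
  list(
    phage    = c("Escherichia coli K-12", "Salmonella enterica LT2",
                 "Pseudomonas aeruginosa PAO1"),
    prophage = c("Escherichia coli O157:H7", "Burkholderia phytofirmans PsJN",
                 "Bordetella petrii DSM12804"),
    plasmid  = c("Cupriavidus metallidurans CH34", "Cupriavidus eutrophus H16",
                 "Rhodococcus erythropolis PR4"),
    GI       = c("Mycobacterium gilvum PYR-GCK", "Mycobacterium sp. KMS",
                 "Streptomyces coelicolor A3(2)"),
    ICE      = c("Ralstonia pickettii 12J", "Cupriavidus metallidurans CH34",
                 "Delftia acidovorans SPH-1"),
    RIT      = c("Aromatoleum aromaticum EbN1", "Caulobacter sp. K31",
                 "Dinoroseobacter shibae DFL12"),
    BIM      = c("Gramella forsetii KT0803", "Cupriavidus metallidurans CH34",
                 "Dinoroseobacter shibae DFL12"))
}

#' Parameters of the synthetic protein corpus
#'
#' The defaults define the package's reference study corpus: 8 families of
#' 12-40 members plus 20 singletons, 280-450 aa sequences over a uniform
#' residue background, expected within-family pairwise identity 0.6, and a
#' planted C-terminal R-H...Y motif (spacing 28-32) in every family.
#'
#' @param n_families Number of planted families.
#' @param family_size_range Inclusive range of family sizes.
#' @param n_singletons Independent random sequences added to the corpus.
#' @param seq_length_range Sequence length range (aa).
#' @param within_family_identity Expected pairwise identity between two
#'   members of the same family (the per-member substitution rate from the
#'   family ancestor is derived from it).  Must exceed the ~0.05 background
#'   identity of uniform random sequences.
#' @param motif_spacing_range R-to-Y spacing range of planted motifs.
#' @param motif_fraction Fraction of families carrying a planted motif (the
#'   first `round(motif_fraction * n_families)` families carry it).
#' @param mge_type_assignment Character vector (length `n_families`) of MGE
#'   types or `"mixed"`; by default types cycle through the seven MGE
#'   classes and the last family is `"mixed"` when there are >= 4 families.
#' @param hosts_per_type Named list of host name templates per MGE type.
#' @param seed Integer seed; fully determines the output.
#' @export
synth_params <- function(n_families = 8L, family_size_range = c(12L, 40L),
                         n_singletons = 20L, seq_length_range = c(280L, 450L),
                         within_family_identity = 0.6,
                         motif_spacing_range = c(28L, 32L),
                         motif_fraction = 1.0, mge_type_assignment = NULL,
                         hosts_per_type = default_hosts(), seed = 1L) {
  if (family_size_range[1] < 1) abort("family sizes must be >= 1")
  if (within_family_identity <= 19 / 380 || within_family_identity > 1) {
    abort("within_family_identity must be in (0.05, 1]")
  }
  if (is.null(mge_type_assignment)) {
    mge_type_assignment <- rep(MGE_TYPES, length.out = n_families)
    if (n_families >= 4) mge_type_assignment[n_families] <- "mixed"
  }
  if (length(mge_type_assignment) != n_families) {
    abort("mge_type_assignment must have one entry per family")
  }
  list(n_families = as.integer(n_families),
       family_size_range = as.integer(family_size_range),
       n_singletons = as.integer(n_singletons),
       seq_length_range = as.integer(seq_length_range),
       within_family_identity = within_family_identity,
       motif_spacing_range = as.integer(motif_spacing_range),
       motif_fraction = motif_fraction,
       mge_type_assignment = mge_type_assignment,
       hosts_per_type = hosts_per_type, seed = as.integer(seed))
}

# Member-to-ancestor retention rate q such that the expected pairwise
# identity between two members is t, under uniform substitution to one of
# the 19 alternative residues: t = q^2 + (1 - q)^2 / 19.
ancestor_retention <- function(t) (1 + sqrt(380 * t - 19)) / 20

#' Mutate a sequence toward a target identity
#'
#' Each unprotected site is substituted with probability
#' `1 - target_identity`; substitutions are drawn uniformly from the 19
#' alternative residues (default) or with BLOSUM62-biased weights.
#'
#' @param seq Protein string (non-empty).
#' @param target_identity Expected fraction of unchanged sites, in (0, 1].
#' @param protected Integer vector of 0-based indices that are never
#'   mutated.
#' @param model `"uniform"` or `"blosum"`.
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, target_identity, protected = integer(0),
                            model = c("uniform", "blosum")) {
  validate_protein_seq(seq)
  model <- match.arg(model)
  if (target_identity <= 0 || target_identity > 1) {
    abort("target_identity must be in (0, 1]")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (length(protected) && (min(protected) < 0 || max(protected) >= L)) {
    abort("protected indices out of range")
  }
  hit <- runif(L) > target_identity
  hit[protected + 1L] <- FALSE
  idx <- which(hit)
  if (length(idx)) {
    cur <- match(chars[idx], AA20)
    if (model == "uniform") {
      offs <- sample(19L, length(idx), replace = TRUE)
      chars[idx] <- AA20[((cur - 1L + offs) %% 20L) + 1L]
    } else {
      B <- blosum62_matrix()[AA20, AA20]
      for (k in seq_along(idx)) {
        alt <- AA20[-cur[k]]
        w <- 2^B[AA20[cur[k]], alt]
        chars[idx[k]] <- sample(alt, 1L, prob = w / sum(w))
      }
    }
  }
  paste(chars, collapse = "")
}

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

#' Generate a protein corpus with planted families
#'
#' Each family grows from a random uniform-background ancestor by per-site
#' substitution ([mutate_sequence()]); the planted motif residues (R, an H
#' anchor immediately after it, and the Y `spacing` residues downstream,
#' near the C-terminus) are protected from mutation in motif-carrying
#' families.  Singletons are independent random sequences.  Metadata (MGE
#' type, host, replicon) follows `mge_type_assignment` and
#' `hosts_per_type`.
#'
#' @param params [synth_params()].
#' @return List with `proteins` (tibble `id`, `sequence`, `length`,
#'   `mge_type`, `host`, `replicon`) and `truth` (tibble `protein_id`,
#'   `true_family`, `mge_type`, `host`, `motif_r`, `motif_y`; motif indices
#'   are 0-based on the ungapped sequence, `NA` when no motif is planted).
#' @export
generate_protein_set <- function(params = synth_params()) {
  withr::with_seed(params$seed, {
    n_motif <- round(params$motif_fraction * params$n_families)
    q <- ancestor_retention(params$within_family_identity)
    prot <- list(); tru <- list()
    for (f in seq_len(params$n_families)) {
      size <- sample_range(params$family_size_range)
      L <- sample_range(params$seq_length_range)
      anc <- strsplit(random_protein(L), "")[[1]]
      protected <- integer(0)
      r0 <- y0 <- NA_integer_
      if (f <= n_motif) {
        spacing <- sample_range(params$motif_spacing_range)
        y0 <- L - sample_range(c(4L, 13L)) - 1L   # 0-based, near C-terminus
        r0 <- y0 - spacing
        if (q * L < spacing + 2 || r0 < 1) {
          abort("identity target incompatible with sequence length: expected conserved sites fall short of the motif span")
        }
        anc[r0 + 1L] <- "R"; anc[r0 + 2L] <- "H"; anc[y0 + 1L] <- "Y"
        protected <- c(r0, r0 + 1L, y0)
      }
      anc <- paste(anc, collapse = "")
      type_f <- params$mge_type_assignment[f]
      for (m in seq_len(size)) {
        id <- sprintf("f%02d_m%03d", f, m)
        seq <- mutate_sequence(anc, q, protected)
        type <- if (type_f == "mixed") {
          sample(c("phage", "plasmid", "GI"), 1L)
        } else type_f
        host <- sample(params$hosts_per_type[[type]], 1L)
        prot[[id]] <- tibble(
          id = id, sequence = seq, length = nchar(seq), mge_type = type,
          host = host,
          replicon = paste0(gsub("[^A-Za-z0-9]+", "_", host), "_rep1"))
        tru[[id]] <- tibble(protein_id = id, true_family = f - 1L,
                            mge_type = type, host = host,
                            motif_r = r0, motif_y = y0)
      }
    }
    for (s in seq_len(params$n_singletons)) {
      id <- sprintf("s%03d", s)
      L <- sample_range(params$seq_length_range)
      seq <- random_protein(L)
      type <- sample(MGE_TYPES, 1L)
      host <- sample(params$hosts_per_type[[type]], 1L)
      prot[[id]] <- tibble(
        id = id, sequence = seq, length = L, mge_type = type, host = host,
        replicon = paste0(gsub("[^A-Za-z0-9]+", "_", host), "_rep1"))
      tru[[id]] <- tibble(protein_id = id,
                          true_family = params$n_families + s - 1L,
                          mge_type = type, host = host,
                          motif_r = NA_integer_, motif_y = NA_integer_)
    }
    list(proteins = bind_rows(prot), truth = bind_rows(tru), params = params)
  })
}

sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
}

# ---- annotated replicons with planted elements and decoys -----------------

feature_row <- function(replicon, start, aa, strand, id, is_tbssr,
                        famint = NA_integer_) {
  nt <- 3L * (aa + 1L)   # CDS including the stop codon
  tibble(replicon = replicon, start = as.integer(start),
         end = as.integer(start + nt), strand = strand, id = id,
         product_len = as.integer(aa), is_tbssr = is_tbssr,
         famint = as.integer(famint))
}

#' Generate an annotated replicon with planted elements and decoys
#'
#' Lays out the planned elements left to right with random intergenic
#' spacers and filler genes.  Planted RIT trios have both pairwise CDS
#' overlaps in 4-8 bp, a common strand and a total span of 3,300-3,700 bp;
#' planted Tn554-like tandems pair a 611-828 aa TBSSR with a 275-425 aa
#' TBSSR on the same strand (optionally followed by a non-TBSSR TnpC);
#' planted BIMs pair a TBSSR with an adjacent partner-family gene.  Each
#' decoy violates exactly one detector rule.
#'
#' @param plan List of element specs, each a list with `type` (`"RIT"`,
#'   `"Tn554"`, `"BIM"` or `"filler"`), optional `decoy` (one of
#'   `"strand"`, `"overlap"`, `"span"`, `"length"`, `"gap"`), optional
#'   `tnpC` (Tn554 only, default `TRUE`) and optional `strand`.
#' @param replicon_id Name of the replicon.
#' @param seed Integer seed.
#' @param bim_partner_famint Family index used for BIM partner genes.
#' @param with_sequence Also generate a random nucleotide sequence of the
#'   replicon length (only needed when repeat scanning is exercised).
#' @return List with `replicon_id`, `length`, `features` (tibble sorted by
#'   start), `planted` (truth tibble: `type`, `members` list column,
#'   `decoy = FALSE`), `decoys` (same shape, the violated rule in
#'   `violation`), and optionally `sequence`.
#' @export
generate_annotated_replicon <- function(plan, replicon_id = "synrep1",
                                        seed = 1L, bim_partner_famint = 45L,
                                        with_sequence = FALSE) {
  withr::with_seed(seed, {
    feats <- list(); planted <- list(); decoys <- list()
    pos <- 500L
    gid <- 0L
    next_id <- function(prefix) {
      gid <<- gid + 1L
      sprintf("%s_g%03d", replicon_id, gid)
    }
    add_filler <- function() {
      f <- feature_row(replicon_id, pos, sample(150:400, 1L),
                       sample(c("+", "-"), 1L), next_id(), FALSE)
      feats[[length(feats) + 1L]] <<- f
      pos <<- f$end + sample(300:900, 1L)
    }
    for (spec in plan) {
      decoy <- spec$decoy %||% NA_character_
      strand <- spec$strand %||% "+"
      if (spec$type == "filler") { add_filler(); next }
      if (spec$type == "RIT") {
        ov <- c(sample(4:8, 1L), sample(4:8, 1L))
        if (identical(decoy, "overlap")) ov[1] <- 12L
        aa <- sample(370:400, 3L, replace = TRUE)
        if (identical(decoy, "span")) aa <- sample(280:300, 3L, replace = TRUE)
        repeat {   # keep the genuine span inside the rule window
          span <- sum(3L * (aa + 1L)) - sum(ov)
          if (identical(decoy, "span") || (span >= 3300 && span <= 3700)) break
          aa <- sample(370:400, 3L, replace = TRUE)
        }
        strands <- rep(strand, 3L)
        if (identical(decoy, "strand")) strands[2] <- setdiff(c("+", "-"), strand)
        s1 <- pos
        f1 <- feature_row(replicon_id, s1, aa[1], strands[1], next_id(), TRUE, 1L)
        f2 <- feature_row(replicon_id, f1$end - ov[1], aa[2], strands[2],
                          next_id(), TRUE, 5L)
        f3 <- feature_row(replicon_id, f2$end - ov[2], aa[3], strands[3],
                          next_id(), TRUE, 2L)
        feats <- c(feats, list(f1, f2, f3))
        entry <- tibble(type = "RIT",
                        members = list(c(f1$id, f2$id, f3$id)),
                        violation = decoy)
        if (is.na(decoy)) planted[[length(planted) + 1L]] <- entry
        else decoys[[length(decoys) + 1L]] <- entry
        pos <- f3$end + sample(800:2000, 1L)
      } else if (spec$type == "Tn554") {
        long_aa <- sample(611:828, 1L)
        if (identical(decoy, "length")) long_aa <- 500L
        short_aa <- sample(300:400, 1L)
        gap1 <- sample(20:200, 1L)
        if (identical(decoy, "gap")) gap1 <- 1200L
        strands <- c(strand, strand)
        if (identical(decoy, "strand")) strands[2] <- setdiff(c("+", "-"), strand)
        f1 <- feature_row(replicon_id, pos, long_aa, strands[1], next_id(),
                          TRUE, 27L)
        f2 <- feature_row(replicon_id, f1$end + gap1, short_aa, strands[2],
                          next_id(), TRUE, 33L)
        members <- c(f1$id, f2$id)
        feats <- c(feats, list(f1, f2))
        pos <- f2$end
        if (isTRUE(spec$tnpC %||% TRUE)) {
          f3 <- feature_row(replicon_id, pos + sample(20:300, 1L),
                            sample(150:250, 1L), strand, next_id(), FALSE)
          feats <- c(feats, list(f3))
          members <- c(members, f3$id)
          pos <- f3$end
        }
        entry <- tibble(type = "Tn554_like", members = list(members),
                        violation = decoy)
        if (is.na(decoy)) planted[[length(planted) + 1L]] <- entry
        else decoys[[length(decoys) + 1L]] <- entry
        pos <- pos + sample(800:2000, 1L)
      } else if (spec$type == "BIM") {
        gap1 <- if (identical(decoy, "gap")) 5000L else sample(20:250, 1L)
        f1 <- feature_row(replicon_id, pos, sample(280:360, 1L), strand,
                          next_id(), TRUE, 19L)
        f2 <- feature_row(replicon_id, f1$end + gap1, sample(200:300, 1L),
                          strand, next_id(), FALSE, bim_partner_famint)
        feats <- c(feats, list(f1, f2))
        entry <- tibble(type = "BIM", members = list(c(f1$id, f2$id)),
                        violation = decoy)
        if (is.na(decoy)) planted[[length(planted) + 1L]] <- entry
        else decoys[[length(decoys) + 1L]] <- entry
        pos <- f2$end + sample(800:2000, 1L)
      } else {
        abort(paste("unknown element type:", spec$type))
      }
      if (runif(1) < 0.6) add_filler()
    }
    features <- bind_rows(feats) |> arrange(.data$start, .data$end)
    total <- max(features$end) + 500L
    out <- list(replicon_id = replicon_id, length = total,
                features = features,
                planted = if (length(planted)) bind_rows(planted) else
                  tibble(type = character(), members = list(),
                         violation = character()),
                decoys = if (length(decoys)) bind_rows(decoys) else
                  tibble(type = character(), members = list(),
                         violation = character()))
    if (with_sequence) {
      out$sequence <- paste(sample(c("A", "C", "G", "T"), total, TRUE),
                            collapse = "")
    }
    out
  })
}

#' Default synthetic replicon suite for element detection
#'
#' Three RIT trios, two Tn554-like tandems (with and without TnpC), one BIM,
#' and six decoys each violating exactly one rule (RIT: wrong strand,
#' overlap out of range, span out of range; Tn554: wrong strand, long TBSSR
#' below the length range; BIM: partner too far away).
#'
#' @param seed Integer seed.
#' @return As [generate_annotated_replicon()].
#' @export
synth_replicon_suite <- function(seed = 1L) {
  plan <- list(
    list(type = "RIT"), list(type = "RIT", strand = "-"), list(type = "RIT"),
    list(type = "Tn554", tnpC = TRUE), list(type = "Tn554", tnpC = FALSE),
    list(type = "BIM"),
    list(type = "RIT", decoy = "strand"),
    list(type = "RIT", decoy = "overlap"),
    list(type = "RIT", decoy = "span"),
    list(type = "Tn554", decoy = "strand"),
    list(type = "Tn554", decoy = "length"),
    list(type = "BIM", decoy = "gap"))
  generate_annotated_replicon(plan, replicon_id = "synsuite", seed = seed)
}
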
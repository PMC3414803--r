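---
title: "Methods: TBSSR family inference, motif detection and element calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TBSSR family inference, motif detection and element calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`famintr` infers families of tyrosine-based site-specific recombinases
(TBSSRs) from sequence similarity, annotates each family's
mobile-genetic-element (MGE) associations, and detects composite
recombinase elements from gene context.  This vignette records the models,
the tunable parameters and the design decisions behind each stage, and
what the synthetic benchmark does and does not demonstrate.

## Similarity model

Every ordered pair of distinct proteins is aligned with exact
Smith–Waterman under affine gaps; there is no heuristic seeding, which is
acceptable at the intended scale (hundreds of sequences).  The default
scoring is BLOSUM62 with gap open 11, gap extend 1 (a gap of length *L*
costs `11 + L`).  Residues outside the 20-letter alphabet are mapped to
`X`, which scores 0 against everything: an unknown residue neither rewards
nor penalises an alignment.

Significance uses the Karlin–Altschul form `bit = (λS − ln K)/ln 2`,
`E = m·n·2^(−bit)` with the gapped-BLOSUM62(11,1) constants λ = 0.267
nats, K = 0.041, where *m* is the query length and *n* the total residue
count of the set.  These are ungapped-theory constants applied to gapped
scores: only the rank order and the cutoff behaviour of E matter
downstream, and both are preserved.  The constants are configurable in
`scoring_scheme()`.  E-values are floored at 1e−200 and hits kept at
E ≤ 0.01.

Edge weights are `min(−log10 E, 200)`; the two directions of a pair are
merged by the maximum (i.e. the smaller E).  The 200 cap keeps weights
finite when E underflows and sits far above the scale set by the 0.01
cutoff (weight 2).

## MCL and ICCC selection

The clustering engine is a from-scratch dense MCL: the column-stochastic
matrix built from the weights plus self-loops is alternately expanded
(squared) and inflated (entrywise power, column renormalisation) until the
largest entry change falls below 1e−8 or 200 iterations elapse
(non-convergence raises a warning and returns the best-effort clusters,
flagged).  Self-loops default to each node's maximum incident weight (1
for isolated nodes), standard practice for E-value graphs that prevents
trivial attractor artifacts.

Pruning (default 1e−5) is applied to the *renormalised stochastic* matrix,
followed by another renormalisation.  Pruning the raw inflated values
instead would be scale-dependent: a uniform column over a k-member clique
has entries 1/k, whose inflated but unnormalised values fall below any
fixed threshold once the inflation exponent is large, deleting whole
columns.  On the stochastic scale the threshold has a stable meaning (a
transition probability) and the unpruned dense reference is matched
exactly on small random graphs.

Clusters are read from the limit matrix as attractor systems (nodes with
positive diagonal, merged when they hold mass on each other); each node
joins the system receiving most of its column mass, ties going to the
system with the lowest-indexed attractor, so the output is a hard
partition.

The inflation factor is swept over 1.2–8.0 in steps of 0.2 (35 values).
Each partition is scored with the intra-cluster clustering coefficient:
intra-cluster edges are binarised, every node of a cluster with ≥ 3
members contributes its local clustering coefficient within the cluster
subgraph (0 if its intra-cluster degree is < 2), and the ICCC is the mean
over those nodes; clusters under 3 members are excluded and an empty set
scores 0.  The published description of the coefficient underdetermines
whether clusters are weighted, so a size-weighted edge-density variant is
available (`iccc(..., variant = "density")`) and the variant used is
recorded on every sweep result; the unweighted form is the default.  The
selected inflation is the ICCC argmax with ties broken toward the lowest
inflation — on clique-like graphs the profile is flat and the sweep
deliberately returns the coarsest granularity that achieves the maximum.

Families are numbered from 0 by decreasing size, ties broken by the
lexicographically smallest member id, so family 0 is always the largest.

## Per-family alignment and the catalytic motif

Guide trees are UPGMA (`hclust(method = "average")`) on
`1 − w/max(w)` distances from the similarity graph (missing edge →
distance 1; members sorted by id first so ties resolve deterministically).
Profiles are merged bottom-up with global profile–profile alignment:
column score is the mean-of-pairs substitution score (gap symbols
contribute 0), gaps are affine with the same penalties as the search
stage, and the traceback prefers diagonal, then vertical, then horizontal
moves.  De-gapping any output row reproduces its input sequence exactly —
this round trip is asserted in the tests.  An external aligner can be
substituted by aligning FASTA out-of-band and constructing the `msa`
object from its rows.

The catalytic-motif scan formalises what is usually done by eye on family
alignments.  A column is *conserved* when its consensus fraction over
non-gap rows is ≥ 0.9 and its gap fraction ≤ 0.2.  Conserved tyrosine
columns are scanned rightmost-first within the C-terminal 35 % of
columns; for each, conserved arginine columns upstream are scanned
nearest-first, and the first pair whose per-row ungapped spacing has a
median in 20–40 residues wins.  Spacing is measured ungapped per row and
summarised by the median because "about 30 residues" is a statement about
sequence space, robust to occasional gappy rows.  The label is `R`, the
consensus residues of the run of conserved columns immediately after the
R (at most 4), then `-Y` — e.g. `RH-Y`; families with no qualifying pair
are reported as "no obvious one".  The 20–40 window, the 35 % window and
the 0.9/0.2 thresholds are declared defaults (`motif_options()`), not
published values; families with fewer than 4 rows are never called.

One known failure mode follows from the scan order: in a small family, a
column can be ≥ 90 % conserved by chance, and when such a column is a
tyrosine a few positions C-terminal of the true catalytic Y, the
rightmost-first scan reaches it first and the 20–40 spacing tolerance
lets it pair with the true arginine.  The call is then still a genuine
conserved R…Y pair, but its Y column is not the planted one.
Exact-column recovery on the default synthetic conditions is therefore
high but not perfect, and `column_to_positions()` should be used to map
calls back to sequence coordinates when comparing against a reference.

## Family annotation

Specificity uses a purity threshold of 0.9 on merged classes, with phage
and prophage counted together as "(pro)phage" (a prophage is an integrated
phage; their integrases are not expected to separate).  Families under 4
members are "small".  Members under 200 aa (strict) are flagged as likely
defective.  Two headline percentages are emitted because the natural
definitions differ: `pct_specific` counts a protein as MGE-type specific
only when its family both reaches the size threshold and classifies
specific; `pct_specific_any` drops the size condition, letting pure small
families (trivially including singletons) count.  The bundled reference
family table records published per-family compositions and manual labels;
the classifier reproduces the manual specific/mixed split on it at the
default threshold, and borderline families are always reported with their
computed purity for transparency.

## Element detection

All rules operate on nucleotide CDS intervals (0-based half-open
internally; GFF3 and BLAST coordinates are converted at the file
boundary).  Overlap is `max(0, min(end) − max(start))`.

* **RIT**: three consecutive TBSSR features, co-oriented, both pairwise
  overlaps in 4–8 bp and total span in 3,300–3,700 bp (±200 bp around the
  ~3.5 kb element size, allowing for end variation).  Both overlaps are
  required — the published inter-gene distances are listed pairwise for
  both junctions.  Members are labelled A/B/C in transcription order.
  Overlapping candidate windows are all reported with a conflict flag.
* **Tn554-like**: an adjacent TBSSR pair with one product of 611–828 aa
  (the long TnpA-like member) and one of 275–425 aa (±75 around ~350 aa,
  which has no published tolerance), co-oriented, intergenic gap ≤ 500 bp.
  The next same-strand non-TBSSR gene downstream within the same gap
  limit is attached as the putative TnpC.  The long member's N-terminal
  extension estimate (`length − 350`) is flagged when ≥ 400 aa.
* **BIM**: a TBSSR adjacent (gap ≤ 300 bp) to a non-TBSSR feature of the
  designated partner family.  The partner family is configuration, not
  inference.

Family identity of members is optional input throughout: detection is
geometry- and length-driven so it works on plain GFF3 without prior
clustering.  Every call's recorded diagnostics re-validate against the
rules (`validate_element_calls()`), and detection is invariant under
reverse-complementing a replicon (strands invert).

The repeat scanner reports maximal exact direct and inverted repeats of
≥ 9 bp with copy starts within 600 bp.  Low-complexity repeats (≤ 2
distinct bases, or one base at ≥ 80 %) are flagged and dropped by default,
which silences homopolymer runs.

## Host network

Hosts are grouped at the genus level — first whitespace token, skipping a
leading "Candidatus" — unless a genus has a single representative, which
keeps its full strain label.  Edge weight is the raw number of shared
families of ≥ 2 members (a singleton family cannot be shared; whether
small families belong in the network is not settled, so the floor is
configurable).  Weights are not normalised — a Jaccard option exists but
is off by default, since raw shared counts are the published convention
for this display.  Components come from igraph; `hub_impact()` recomputes
them after removing named nodes.

## The synthetic corpus

The generator emulates the kind of reference set the pipeline is meant
for, with full planted truth.  Defaults (the package's study conditions):
8 families of 12–40 members plus 20 singletons, lengths 280–450 aa (the
working size range of full-length TBSSRs), uniform residue background,
motif planted in every family with R–Y spacing 28–32 and an H anchor
after the R.  `within_family_identity` (default 0.6) is the expected
*pairwise* identity between members; the member-to-ancestor retention
rate *q* solves `t = q² + (1−q)²/19` under uniform substitution.  The
pairwise reading is what the recovery benchmarks measure, and 0.6 places
families far above the ~0.05 background identity of uniform sequences
while leaving unprotected columns well below the 0.9 conservation
threshold, so motif detection is genuinely discriminative rather than
trivial.  Family ancestors are independent — no between-family homology
is planted — and there is no indel evolution, so family alignments are
gap-free and the planted motif columns are recoverable exactly.

Synthetic replicons lay out planted RIT/Tn554-like/BIM elements with
randomised geometry inside the rule windows, interleaved with filler
genes; each decoy violates exactly one detector rule (wrong strand,
overlap or span out of range, long member too short, partner too far).
CDS "translations" are lengths only — detector rules use coordinates, not
codons — and nucleotide sequence is generated only where repeat scanning
is exercised.

What passing these benchmarks shows: the pipeline recovers clique-like
families (adjusted Rand index ≥ 0.9 on the default corpus), the motif
scan attains high sensitivity and a low false-positive rate when
conservation contrasts are real, and the detectors are exact on elements
that respect the published geometry.  What it does not show: behaviour on
real corpora with between-family homology gradients (the chaining that
makes large mixed families), indels, compositional bias, or annotation
noise in real GFF3 — the generator has a "confounder" knob only in the
sense that identity and sizes are configurable, and no claim is made that
ICCC selects the published inflation on real data.

## Numerical and engineering choices

* Problem sizes: the bundled analyses use a 189-protein corpus
  (~70 k residues, ~26 k alignments, a 35-point sweep over a 189-node
  dense MCL), chosen so a full run completes in a few minutes on one CPU.
* Alignment kernels (pairwise Smith–Waterman, profile NW) are in C++;
  everything else is plain R on tibbles.
* Traceback tie-breaks (diagonal, then up, then left) and the id-sorted
  tie-breaks in UPGMA, family ranking and attractor assignment make every
  stage deterministic; the only randomness in the package is the
  synthetic generator, which is fully determined by its seed.
* Degenerate inputs: empty sequences error; single-node graphs cluster to
  a singleton; all-gap alignment columns get consensus `NA`; a fully
  pruned MCL column restarts at its self-loop.
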
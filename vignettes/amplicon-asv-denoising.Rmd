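---
title: "Abundance-based ASV denoising with provenance-linked output"
author: "asvgraph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance-based ASV denoising with provenance-linked output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asvgraph)
```

## The model

`asvgraph` denoises marker-gene amplicon read pairs without a
parametric error model.  It rests on two assumptions about sequencing
error:

* an error-read is *less abundant* than the biological variant it
  descends from, because errors are positionally dispersed while a real
  variant sits at a fixed position in the amplicon; and
* an error-read is *similar* to its template — almost always within a
  single edit over the combined forward + reverse sequence.

Those assumptions drive a two-step procedure per sample.  First, exact
grouping: at least `minIdentical` (default 3) identical
forward/reverse pairs form an ASV object, and the remaining pairs are
treated as candidate error-reads.  Each of those is absorbed into the
closest ASV if its cumulative (forward + reverse) edit distance is at
most `errorCorr` (default 1), incrementing the ASV's read count but
never altering its sequences; otherwise it is discarded as
sample-specific noise.  Second, whole-ASV correction: amplicons that
systematically accumulate errors can form *erroneous ASVs*, so ASVs
below `minPerT` percent (default 0.1 %) of the sample's ASV-associated
reads are merged — counts summed, abundant sequences kept — into the
highest-ranked ASV within `errorCorr` edits.  A low-abundance ASV that
merges nowhere may still be real biology, so it is labelled
*provisionally rejected* and retained in every output rather than
deleted; downstream queries can then test whether it recurs across
samples (recurrent pairs are likely real, sample-unique ones noise).

Chimeras are flagged by a purely compositional rule: an ASV whose
forward sequence equals one ASV's forward and whose reverse equals a
*different* ASV's reverse, with both parents at ≥ 2× its read count, is
typed as chimeric, excluded from classification and abundance tables,
but kept in the serialized graph.

## The distance primitive

All comparisons use a *k*-bounded Levenshtein distance: a unit-cost
edit distance computed in a diagonal band of half-width *k*.  Inside
the band the result is exact (any cell value is at least its diagonal
offset, so no optimal path at distance ≤ *k* leaves the band); beyond
it the function reports only "exceeded", which is all the callers need.
Denoising uses *k* = 1, classification *k* = 50.

Fixed-length trimming introduces one artefact the plain distance would
mis-score: a single internal insertion or deletion shifts every
subsequent base, so the read and the reference agree up to the indel
and then run out of register, one overhanging the other's end.  The
`end_tolerant_distance()` variant therefore charges nothing for gaps
confined to the trailing end of either sequence (the minimum over the
last row and last column of the dynamic program, rather than the
corner cell).  We interpret out-of-frame "phantom" indel handling as
exactly this end-gap-free scoring — the natural consequence of
fixed-length trimming — and document it as a design choice; unit costs
(match 0, mismatch/indel 1) are used throughout, as no cost matrix is
specified for the method.  One corollary worth knowing: with sequences
of unequal length, a trailing overhang is always free, so the variant
is asymmetric in spirit ("how well does one read fit the start of
another") even though it is symmetric in its arguments.

## Parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `minIdentical` | 3 | read pairs | identical pairs forming an initial ASV |
| `minPerT` | 0.1 | % of ASV-associated reads | merge threshold for erroneous ASVs |
| `errorCorr` | 1 | edits (fwd + rev combined) | rescue and merge distance |
| `identLvl` | 100 | % identity | ASV formation; only exact matching (100) is supported |
| `classifyRatio` | 0.8 | fraction | per-rank count-weighted majority needed to assign |
| `for_read_len`, `rev_read_len` | 70/70 | nt | fixed trim lengths; omit `rev_read_len` for single/merged reads |
| bound | 50 | edits | classifier distance cap |
| mismatch cap | 15 | % of combined length | hit-list inclusion cap |

`errorCorr` is read as *cumulative* across the pair: one mismatch in
the forward **or** the reverse read, not one in each.  The same
cumulative reading is applied to ASV merging, so the single flag
governs both error-handling steps.

## Taxonomic assignment

The lookup table collapses trimmed reference regions to unique
(forward, reverse, lineage) entries with occurrence counts.  For an
ASV, every entry within the bound and the 15 % mismatch cap becomes a
hit; only hits at the *minimal* observed distance vote (worse strata
are stored as provenance but do not dilute the vote).  The best
identity caps the deepest assignable rank — species only for a perfect
match naming a single species, genus at ≥ 0.95, family at ≥ 0.92,
order below.  The interval boundaries are taken as closed lower bounds
(0.95 is genus, 0.92 is family), a choice the method description
leaves open.  Walking from domain toward the cap, a rank is assigned
when the leading taxon's share of reference counts among voting hits
reaches `classifyRatio`; that share is exported as the per-rank
confidence.  The consensus-ratio semantics themselves are not fully
specified by the method's published description (it defers to an
earlier implementation), so this package defines `classifyRatio` as
the count-weighted majority fraction per rank — the definition is part
of the package contract and is what the monotonicity property tests
exercise.  Identity is computed over the combined trimmed length
(forward + reverse scored jointly).

Reference primer sites are located with degenerate-primer matching: a
position matches when the read base lies in the primer code's IUPAC
set, at most one mismatching position is tolerated, and the 3'-most
primer base must match perfectly or be the G/T wobble pair (the
mismatch that still primes).  In alignment mode the primer columns are
taken as consensus once the same start/stop columns have been seen
1,000 times; small references never reach that count, so the modal
column pair at end-of-stream is used instead — required for any
desk-scale reference.  Occurrences are counted cumulatively per column
pair (no reset on a discordant row).  The region of interest excludes
the primer columns themselves, and the reverse region is stored
reverse-complemented, i.e. in read orientation, so classifier
distances compare like with like.

## Numerical and procedural choices

* **Ranking ties.**  ASVs are ranked by read count descending with
  ties broken lexicographically by (forward, reverse); this makes
  denoising independent of input order, which the tests assert.
* **Single-pass merging.**  The merge threshold and ranking are
  computed once; absorptions do not re-rank or re-thresholded the
  remaining ASVs.  An iterative variant would only differ when a merge
  lifts an ASV across the threshold mid-pass, a regime the abundance
  assumptions already treat as unstable.
* **Small groups.**  Groups of 2 identical pairs (below
  `minIdentical`) are routed through singleton rescue as individual
  pairs rather than discarded outright.
* **Degenerate inputs.**  Empty samples yield empty ASV tables with a
  warning, not errors.  Undefined metrics (zero denominators in
  precision/recall, zero off-diagonal Gram mass in the modified RV)
  are reported as `NA`, never silently as 0 — a pair of orthogonal
  one-hot composition vectors genuinely has no off-diagonal
  information to correlate.
* **Modified RV orientation.**  Compositions enter as columns over a
  taxa axis (rows = taxa), aligned between the two matrices by the
  union of taxon labels with zero fill; a single sample is a one-column
  matrix.  This orientation makes the single-sample case well defined.
* **Determinism of identifiers.**  ASV node IRIs are digests of
  (sample, forward, reverse) and the BIOM date is injectable, so
  re-runs are byte-identical — asserted by tests.

## Serialization

The graph model has one `Library` per run, `Sample` nodes per mapping
entry, and one node per ASV object typed by status (`ASVSet`,
`RejectedASVSet`, `RejectedAsChimera`), with shared `Sequence` nodes,
an `ASVAssignment` per classified ASV and a
`Provenance`/`ProvenanceClassification` chain carrying the complete
command arguments.  Classes are UpperCamelCase, properties
lowerCamelCase, under a single project namespace; the full external
ontology is deliberately not imported.  The Turtle writer emits one
triple per line and the bundled reader reconstructs the graph
losslessly; the files load into any triple store for real SPARQL use,
while `shared_asvs()` and `rejected_recurrence()` provide the routine
cross-sample queries in-process.  The BIOM 1.0 export is a sparse
"OTU table" readable by standard BIOM readers, extended with a
top-level `args` object and per-row sequences, taxonomy, confidence
and status; stripping the extensions leaves a plain BIOM 1.0 document.

## What the mock generator emulates — and what it does not

`mock_spec()`/`generate_references()`/`generate_reads()` emulate
Mockrobiota-style benchmark communities: even or staggered (log-spaced
over three orders of magnitude) profiles of ~1.5 kb templates carrying
515F/806R-style degenerate primer sites, multiplexed barcoded reads
with configurable substitution/indel rates, a configurable fraction of
chimeric pairs, and multi-copy operon variants differing by one
in-region base.  Every artefact derives from one integer seed and is
byte-reproducible.

Deliberate simplifications, which bound what green tests prove about
real data: per-base errors are uniform (no quality-score model, no
motif-dependent error hot-spots), PCR amplification bias is absent,
errors are injected only into the template-derived portion of a read
(so primer/barcode loss is not simulated), primer realizations are
fixed per reference set, and reference lineages are strictly
hierarchical with one genus per taxon.  Perfect precision/recall on
these fixtures demonstrates that the algorithms implement their
contracts, not that real MiSeq runs will classify perfectly.

## Problem sizes

The test-suite and acceptance runs use a 20-taxon even mock at 1,000
read pairs per taxon (70 + 70 nt reads) for the recovery properties,
0.1 % substitution noise for the error-model properties, a 10-taxon
mock at 5 % chimera fraction for the chimera rule, and 6-taxon
replicate sets for the cross-sample queries; the distance primitive is
checked exhaustively over all DNA string pairs up to length 4 and on
10,000 random pairs up to length 50.  These sizes were chosen as the
smallest at which every property is non-trivially exercised (e.g. the
staggered recurrence fixture places its rarest taxon between the
formation minimum and the merge threshold).

## Known limitations

* `identLvl` other than 100 is rejected: similarity-threshold OTU
  formation is out of scope by design.
* Single-read mode disables chimera detection (the rule needs both
  reads) and classifies on the forward sequence alone.
* Barcode matching is exact; only primers tolerate a mismatch, and
  primer matching is positional (no indels in the primer itself).
* The Turtle reader covers the subset this package emits (one triple
  per line); it is a round-trip tool, not a general RDF parser.
* Reads are never merged; pre-merged reads are accepted via
  single-read mode instead.
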
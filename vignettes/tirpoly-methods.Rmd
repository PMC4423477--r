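---
title: "Detecting DNA transposon insertion and excision polymorphisms between closely related genomes"
author: "TIRpoly authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TIRpoly methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cut-and-paste (Class II, TIR-order) DNA transposons leave characteristic
sequence signatures. An insertion duplicates its target site, so the new
locus reads flank–TSD–element–TSD–flank while the orthologous locus in a
sister species carries a single TSD copy. An excision removes the element
and leaves a double-strand break whose repair determines the footprint:
non-homologous end joining can restore exactly the two TSD copies
("perfect excision"), single-strand annealing deletes flanking sequence,
and synthesis-dependent strand annealing copies in foreign "filler" DNA;
combinations occur. A special case, the precise excision (element plus one
TSD removed), restores the pre-insertion state and is therefore
*indistinguishable from an insertion in the other species* by comparative
analysis alone — the package deliberately reports such loci as insertions.

Given two assemblies of species that diverged recently enough to align
(sub-percent substitution divergence) yet long enough ago to accumulate
transposition events, TIRpoly extracts presence/absence polymorphisms,
decides which species gained or lost the element and how, and computes the
downstream activity statistics.

# Pipeline model and assumptions

## Anchoring and windowed alignment

The query genome is cut into 5-kb fragments (the short terminal fragment is
kept). Each fragment is located on the target by k-mer seed voting (k = 14,
diagonal bins of 1 kb) and verified by a banded local alignment. Anchors
must lie on the majority chromosome, in forward orientation, at ≥ 96%
identity, and on the longest strictly increasing chain of target positions
(an automated stand-in for manual collinearity checking; inversions and
translocations are out of scope by design). Anchor identity is computed per
matched segment — alignment-gap runs longer than 50 bp are excluded from
the columns — so a transposon-sized insertion inside a fragment does not
destroy its anchor; this mirrors the per-HSP identity a BLAST-based
anchoring would report.

Each anchored fragment seeds a 12-kb window pair (fragment + 7-kb 3'
extension, so consecutive windows overlap by 7 kb). Windows are aligned
with an exact affine-gap local (Smith–Waterman) aligner: match +5, mismatch
−4, and a gap of length L costs 30 + 0.1·L. The tiny extension penalty
makes one long gap far cheaper than several short ones, which is exactly
what presence/absence polymorphisms look like. Ns score as mismatch against
everything, including other Ns. The DP is implemented in C++ over a
diagonal band; the pipeline derives the band from chained seeds with a
300-bp margin (exact within the band, and verified against the full
quadratic DP in the tests), while `band = NULL` runs the full matrix. The
target window carries 3.5 kb of extra slack beyond the 12 kb because the
homolog of the query window is longer whenever the target holds insertions;
without the slack a window can end inside an unaligned insert.

Scores are floating point (the gap extension is fractional); score
comparisons in tests use a tolerance of 1e-6.

## Assembly of window alignments

Windows are assembled left to right with a cursor: each new window takes
over from a cut position chosen where *both* windows are locally gap-free
(±10 columns), preferring the side of the higher-identity window, and never
behind coverage that has already been emitted. Window pairs whose target
intervals disagree by more than 10 kb are truncated to non-overlapping
cores and the conflict is logged. Blocks that abut exactly in both genomes
are fused again before scanning, so events near assembly seams keep their
flanking context. Target-coordinate monotonicity is enforced; rare blocks
violating it are dropped and logged.

## Event extraction and filters

Maximal gap runs strictly longer than 50 bp in either row become events
attributed to the sequence-bearing species. Three further rules follow the
established filtering scheme:

* events separated by fewer than 4 aligned columns are merged (the spacer
  bases are included in the fused event);
* events whose extra sequence or immediate flanks (10 bp) touch an N run
  are set aside — they are still counted for the hidden-TE extrapolation,
  as are events consisting of more than 80% Ns (strict threshold);
* every event must be embedded between at least 200 aligned columns with
  more than 90% perfect matches on both sides. "Aligned" is interpreted
  per indel: gap runs at or below the 50-bp event threshold (background
  indels, small fillers) neither break a flank nor count towards it; only
  another candidate indel or the end of the aligned block ends a flank.
  This keeps the spirit of the rule — the event must sit in confidently
  aligned sequence — without rejecting every excision that created a small
  filler next to the main gap.

One further guard addresses an artifact of the low gap-extension penalty:
a long gap can be split in two when a handful of opposing bases (typically
filler DNA) half-aligns against the gap interior, since the split costs
only one extra gap opening. Gap runs separated by ≤ 30 columns that are
not confidently aligned (match fraction < 0.9, or containing
opposite-direction gap columns) are therefore fused back into one run
before the size filter. Clean spacers are never fused, so the strict
"< 4 aligned bp" merge rule remains the contract for well-aligned
neighbours.

## Classification

Each event's extra sequence is annotated against the TE library (all local
hits of ≥ 50 alignment columns at ≥ 70% identity, identity defined as
matches over all columns including gaps; overlapping same-family hits are
merged). Hits also report their consensus coordinates, from which
full-length element borders are extrapolated when only a few terminal
bases were clipped (≤ 15 bp) — local alignment and gap-placement ambiguity
routinely shave element termini.

Footprints are measured on homologous context windows: the bearing-side
window B and the empty-side window E start and end at orthologous aligned
columns (anchored ~300 columns beyond the event), so length(B) −
length(E) = removed − filler *exactly*. The replacement is resolved by
maximal flank extension: the longest matched prefix and suffix of B
against E determine the removed span and the filler string. Because
boundary placement is not always uniquely determined by the sequences
(a filler starting with the same base as the element shifts the boundary),
both the classifier and the simulator's ground-truth log use this same
normalization — exactly the convention of indel left-alignment in variant
calling. On divergence-free data the matching is exact; on diverged data
isolated substitutions are absorbed when at least 6 of the following 8
bases match (past a real breakpoint agreement drops to ~25%, which stops
extension almost surely).

The decision tree (first match wins; slack 3 bp for annotation-border
fuzz; L is the superfamily TSD length):

1. *internal deletion* — the annotation continues into both bearing flanks
   (checked against the consensus coordinates, which say how much element
   is expected on each side);
2. *insertion* — TSD present in the bearing species (exact for the fixed
   2–3-bp motifs TA and TAA/TTA; one mismatch allowed between the copies
   of 8–9-bp variable TSDs), no filler, and removed = element + exactly
   one TSD (tolerance min(3, L−1), so a perfect excision of a TA-TSD
   element cannot masquerade as an insertion);
3. *perfect excision* — removed = element exactly (the tandem TSD remains
   at the empty site);
4. *excision with deletion* — removed exceeds element + TSD; deleted bp =
   removed − element − L;
5. *excision with filler* / 6. *both* — a filler string is present,
   without/with additional removed flank;
7. *unclear* otherwise. Events without TE homology covering ≥ 80% of the
   extra sequence receive no transposition verdict.

## Family discovery

Events without library homology are searched against the whole genome
(seed-and-extend, k = 12). Segments with ≥ 15 near-full-length copies at
≥ 85% identity are putative TEs: the top 15 hits are extracted with 300 bp
of flanking sequence ("a few hundred bp"; 300 is this package's fixed
choice), multiply aligned with a center-star strategy (adequate at ≥ 85%
pairwise identity; pairwise steps use Biostrings' global aligner), and the
element core is the maximal column interval where ≥ 50% of rows are
non-gap and ≥ 70% of non-gap characters agree — the unrelated flanks
diverge, so an alignment that is conserved wall to wall has indeterminable
borders and is rejected. The consensus is the strict per-column majority
(ties alphabetical). Conserved target-site bases can survive at the core
edges (all copies of a TA-specific family are flanked by TA), so small
symmetric offsets (0–3 bp) are scanned for a TIR match and the consensus
is trimmed to the element proper; the TIR assigns the superfamily (DTM,
the least constrained profile, is the fallback when no TIR matches — such
consensus sequences would be curated by hand in practice). Discovery
iterates longest-first until a pass adds no family. The discovery identity
is computed against the query segment (the alternative — pairwise among
hits — is not what the iterative search needs).

# The simulator

`simulateGenomePair()` generates the study conditions: a random ancestor
(default 2 Mb at GC 0.44), five planted families (one per superfamily,
with the proper TIR termini and TSD behaviour; lengths 250–1200 bp
reflecting the dominance of non-autonomous elements), 20 ancestral copies
per family, divergence by independent substitutions (default 0.35% per
branch, i.e. 0.7% pairwise — chosen to make alignment non-trivial yet
anchorable) and small background indels (1–10 bp at 5e-5 per bp per
branch, never above 50 bp so background cannot mimic a TE polymorphism),
then 150 post-divergence insertions, 50 excisions, optional precise
excisions (default 0), 10 internal TE deletions, and 20 assembly gaps
(60–2000 Ns) in genome B, a quarter of them centred on planted copies.

Excision footprints draw from a four-way mix. The observed outcome counts
(8 perfect, 43 with deletion, 58 with filler, 9 both, out of 94) are not
mutually consistent as stated — they sum to 100 events — so the defaults
pin the two quantities reported as fractions of 94 (p_perfect = 8/94,
p_both = 9/94) and split the remaining mass 34:49 between deletion-only
and filler-only. Flanking deletions are geometric with mean 18 bp, with a
rare (1%) extreme component drawn from 1–3 kb — a two-component law
reproduces both the reported mean and the single multi-kb case. Fillers
are geometric with mean 13 bp clipped to 1–123 bp (a uniform law on that
range would have mean 62 and contradict the reported mean of 13). Fillers
are copied from a random donor locus of the same genome (SDSA semantics).
Deletions are one-sided by default (side uniform); a config switch enables
two-sided deletions, since no per-side breakdown is reported.

All coordinates are tracked through an explicit edit list, so every truth
record carries final coordinates in both genomes; excision rows
additionally log the normalized deleted/filler quantities recoverable from
the sequences (see above). All randomness flows from R's RNG seeded once
from `config$seed`; fixtures are byte-identical per seed.

What the simulator does *not* emulate: retrotransposons, nested
insertions, CACTA subterminal repeat arrays, rearrangements
(inversions/translocations), region-specific substitution rates, and
assembly errors other than N gaps. Passing tests therefore demonstrate
correct behaviour of the detection logic under the stated event model, not
robustness to every artifact of real assemblies — on real data the
"unclear" class grows and manual review remains advisable.

# Statistics

Under the replication-fork proliferation model, an element excises from a
replicated chromatid and reinserts ahead of the fork: one daughter
chromatid keeps donor + new copy, the other has the excised donor + new
copy. A fixed lineage samples one chromatid per event, so a cross-species
comparison observes the insertion always and the excision with probability
1/2 — the expected insertion:excision ratio is 2:1 (and between 1:1 and
2:1 if some transpositions happen outside S phase).
`simulateGameteTransmission()` implements exactly this sampling.

`ratioTest()` tests observed counts against the expectation with a
two-sided exact binomial test of the insertion count at p₀ =
expected/(expected+1) — the defensible default, since the published
"Fisher's exact test" never states its contingency table. An exact 2×2
test (observed vs rounded expected counts) is co-reported for
transparency; the package does not claim to reproduce the published
p-values, only the ratios.

Relative activity is moved copies / total copies of a family (moved counts
both species' events, since an extra sequence in one species may mean an
insertion there or an excision in the other); relative abundance is family
copies / all DNA transposons. Groups I/II/III split active families at the
medians of the two quantities (the published grouping draws no explicit
boundaries; the median split is this package's convention, overridable).

`fixationRate()` divides fixed events by generations since divergence (for
neutral events the population size cancels); the reciprocal "one event per
N individuals" is computed from the rate *as reported* (rounded to three
digits), matching how such figures are quoted.

The hidden-TE estimate maps 500 bp of both flanks of every N run > 50 bp
onto the other genome (hits ≥ 400 bp at ≥ 95% identity, same orientation,
within 10 kb) and screens the intervening segment for TE homology; the
TE-positive fraction of mappable gaps extrapolates to all gaps and to the
N-rich polymorphism count.

Gene context assigns each polymorphism exon > intron > upstream (1 kb 5'
of the coding sequence, strand-aware) > downstream (500 bp 3') >
intergenic; among overlapping genes the closest coding sequence wins, ties
to the smaller gene id; gene models mentioning "transpos" are removed
first.

# Numerical choices and problem sizes

* Coordinates are 1-based inclusive throughout (the IRanges/Biostrings
  convention of this ecosystem); FASTA and GFF3 enter through Biostrings
  and rtracklayer.
* Alignment scores are doubles; equality in tests uses 1e-6.
* Consensus ties break alphabetically; overlap cuts prefer the
  higher-identity window; all other ties are resolved by position order.
* The test suite validates the aligner against an independent quadratic
  DP oracle on 500 random pairs of up to 100 bp, runs the full pipeline on
  a 2-Mb pair under the default conditions (recovery of planted events
  with correct verdicts) and on an 800-kb divergence-free pair (exact
  recovery of insertions and perfect excisions), and checks the footprint
  calibration on 10,000 draws. These sizes keep the default suite within
  a practical runtime while exercising every stage at full fidelity;
  larger genomes only add more of the same windows.

# Known limitations

* Precise excisions are reported as insertions of the other species — an
  identifiability limit, not a bug; the simulator plants them under their
  own label so the forced relabeling is measured, not hidden.
* A filler that substantially re-aligns against the excised element can
  still fragment an event despite the low-identity-spacer guard; such loci
  surface as unclear or as two partial events (a small fraction of filler
  excisions in the default simulations).
* Large deletions removing both flanks of an element are indistinguishable
  from random deletions that happen to contain a TE; they end up unclear.
* The aligner is collinear: inversions, translocations and nested events
  are out of scope.
* Family discovery assigns superfamilies only via terminal TIR matches;
  consensus sequences without a recognizable TIR default to DTM and would
  need manual curation.
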
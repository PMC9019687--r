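---
title: "Repeat discovery and assembly curation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat discovery and assembly curation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telosv)
```

# The problem

Finishing a small eukaryotic genome telomere-to-telomere is dominated by a
handful of repeat structures that defeat both short-read assembly and naive
polishing: chromosome-end telomeric tandem arrays, a single very large rDNA
tandem array, LTR retrotransposons whose two long terminal repeats are
nearly identical, multi-kilobase duplicated segments parked in subtelomeric
regions at near-100% identity to their paralogs, and a mating-type locus
whose ~19-kb cassette region flips orientation between two ~2-kb inverted
repeats. Each of these produces a characteristic artifact: collapsed
duplications, dropped retroelements, under-counted array copy numbers,
over-assembled ends, and "structural variants" between two assemblies that
are really misassemblies or a mating-type switch rather than biology.

`telosv` implements the full analysis loop for this situation: detectors
for each repeat class, an evidence-based curation layer driven by long
reads, assembly-to-assembly comparison with variant classification, and a
synthetic-genome generator that plants every feature class with exact
ground truth so each detector can be validated end-to-end.

# The synthetic study system

`synthetic_config()` defaults describe the study conditions:

* three 300-kb chromosomes of i.i.d. background sequence at 48% GC;
* every chromosome starts with `[ACCCCGCC]20` and ends with
  `[GGCGGGGT]20` (160 bp per end; the two units are reverse complements of
  one another);
* one rDNA tandem array of 20 copies on one chromosome (2-kb unit by
  default; `rdna_unit_length = 8145` gives the full-scale ~163-kb array);
* five LTR retrotransposons: 322-bp LTR pairs flanked by the target-site
  motifs `TCTTG`/`CAACA`, a single ORF encoding a 1,417-aa polyprotein,
  three intact and two degraded copies (a nonsense SNP near the ORF
  midpoint plus an upstream 1-bp frameshift, placed so no residual open
  frame can reach polyprotein scale), on mixed strands;
* three subtelomeric duplicated-segment pairs of 27,850 / 5,100 / 2,500 bp.
  The large pair differs by exactly 4 substitutions and one 1-bp gap; the
  divergence of the two smaller pairs is not dictated by the study system,
  so the generator fixes 6 substitutions + two 1-bp gaps and
  3 substitutions + one 1-bp gap respectively. The 5,100-bp pair ends in
  `[ACCCCGCC]4`, the 2,500-bp pair in the degenerate 7-mer `[ACCCGCC]3`;
* a mating-type locus of 2-kb inverted repeats around a 19-kb invertible
  region;
* poly(GC), short-tandem-repeat, and homopolymer tracts.

Two geometric choices matter for testing. First, every planted tandem
array is wrapped in single pad bases that break the repeat periodicity at
its boundary, and divergence sites of each duplicated-segment pair
alternate between the two outer fifths of the segment (away from
boundaries, terminal motifs, and the central window that the collapse
defect removes). This makes planted coordinates exactly recoverable, so
the tests can assert recovery at zero tolerance rather than "close
enough". Second, read length is capped at a third of the chromosome so
copy-number estimation from reads stays non-trivial.

What the generator does **not** emulate: PacBio chemistry and quality
scores, chimeric or strand-switching reads, diploidy, GC-coverage bias,
and the sequence content of real rDNA or retroelement families (units are
random sequence of the right geometry). Passing tests therefore
demonstrate correctness of the algorithms under the stated error models,
not performance on real flow-cell data.

## Read simulators

`simulate_long_reads()` draws lengths from a normal distribution (default
25 kb ± 6 kb) and applies an indel-dominant error process (0.2%
substitutions, 0.6% insertions, 0.6% deletions per base — about 1.4%
total). `simulate_short_reads()` applies background substitutions (0.1%)
everywhere *except* inside maximal G/C runs of more than 10 bases, where
every read fully covering the run is corrupted with probability
`error_prob` towards a per-locus fixed wrong allele (one base shrunk,
extended, or substituted). The fixed wrong allele is the essential
feature: it makes short-read errors *systematic*, so naive majority
polishing is corrupted inside poly(GC) runs while remaining correct
everywhere else. The real mechanism behind such errors is not established;
this model is this package's construction and is configurable.

# Detectors

## Tandem arrays

Detection is two-tier. Small periods (4–64 bp) are found by scanning, for
each period p, maximal runs of positions with `s[i] == s[i+p]`; a
mismatch gap is bridged only when a near-full unit of matches flanks it on
*both* sides, so chance matches next to an array cannot drag its boundary
outward. Large periods (65–10,000 bp) are found from the histogram of
spacings between repeated 13-mers, verified and trimmed by the same lag
profile. Trailing partial units are kept only when at least half a unit is
present. Units are reported in canonical form (lexicographic minimum over
all rotations of the unit and its reverse complement), copy number as
span/unit length to one decimal, and purity as one minus the mismatch
fraction. Overlapping calls resolve by purity, then length, then smallest
period — so a pure array is reported at its fundamental period, not a
harmonic.

`call_telomeres()` restricts to arrays anchored within 100 bp of a contig
terminus whose canonical unit matches the expected telomere unit.
`estimate_copy_number_from_reads()` implements the orthogonal, read-based
estimate: each read of ≥ 20 kb containing both unique flanks walks the
array greedily unit-by-unit, fitting each unit into a slightly longer
window with an edit tolerance of max(1, 5% of unit length) — which
reduces to the "one edit per unit" rule for the 8-bp telomere unit — and
the estimate is the median of per-read integer counts. When no read spans
the array, the result is an explicit "no estimate", never a number.

## LTR retrotransposons

`find_ltr_pairs()` anchors co-oriented repeats by shared 21-mers at
start-to-start distances compatible with 200–600-bp LTRs spaced
2–8 kb apart, extends each chained candidate to its maximal exact
boundaries, and verifies identity ≥ 0.95 by banded alignment. Each repeat
copy joins at most one pair, greedily by identity, then span, then
leftmost coordinate — ties between identical within-element and
cross-element pairings are avoided in practice because element copies
differ slightly while an element's own two LTRs are identical at
insertion. Strand is resolved by which orientation puts `TCTTG`
immediately 5′ of the upstream LTR and `CAACA` immediately 3′ of the
downstream LTR (exact 5-mers, zero gap, zero-mismatch default, as the
motifs are printed without tolerance).

Intactness is deliberately two-tier: `structural_intact` (both LTRs plus
an internal region) versus `coding_intact` (a single ORF of at least
`min_aa` amino acids in a six-frame scan of the internal region). The
default `min_aa = 1000` sits below the 1,417-aa polyprotein so scaled
elements still qualify. This separation exists because a retroelement can
be structurally complete while SNPs or indels have broken its ORF into
pieces; conflating the two tiers loses exactly the distinction the
curation workflow needs.

`compare_elements()` globally aligns two full element sequences with a
gap-consolidating traceback (among co-optimal paths, gaps extend rather
than fragment), counts SNPs and indels, and translates in-frame
insertions after sliding them to the codon frame of the element's main
ORF among their equivalent placements — gap placement inside repetitive
context is otherwise arbitrary and would scramble the peptide.

## Subtelomeric duplicated segments

`find_duplicated_segments()` compares all pairs of 50-kb end windows (the
subtelomere has no standard numeric definition; 50 kb covers the largest
expected segment with margin). Shared 15-mers capped at 4 occurrences per
window are chained by diagonal; a longest strictly-increasing subsequence
of each cluster's anchors sets phase-consistent endpoints (tandem motifs
inside a segment otherwise contribute off-diagonal anchors that corrupt
the chain ends). Chained spans are extended to maximal exact boundaries
and aligned with a banded global aligner whose band is the length
difference plus 32; terminal indel columns of that alignment are trimmed
as boundary artifacts. Divergence is reported exactly as the alignment
counts it: identity = 1 − (mismatches + gap columns)/columns, with the
denominator including gap columns. The minimum reported length (2 kb)
sits just below the smallest expected segment; inverted-orientation
duplications are reported but flagged, since the expected segments are
co-oriented. The large-period tandem tier requires ≥ 3 copies precisely
so these two-copy segment pairs are never mistaken for tandem arrays.

`detect_terminal_motif()` searches the 3′-terminal 200 bp of each copy
for tandem runs of the full telomere unit or its degenerate 7-mer,
calling a motif only when strictly more than 2 copies are present.

## Mapping, polishing and curation

The built-in mapper is deliberately a *toy*: it exists so the pipeline is
self-contained on synthetic data, and its contract — not its throughput —
is the point. Short reads are placed by three exact 21-mer seeds and a
banded fitting alignment; a tie between distinct best loci leaves the
read unmapped and counted as ambiguous, which is the honest answer inside
two-copy repeats. Long reads chain reference-*unique* 21-mer anchors,
fill between anchors with banded alignment, and extend the ends only
while the alignment keeps scoring (X-drop, capped at 6 kb) — so a read
whose genome lacks an assembly's junction stops at that junction instead
of spanning it, which is exactly the property junction auditing needs.
Pileup construction left-normalizes indels through homopolymer context so
all reads vote on the same column.

`polish_consensus()` applies the short-read pileup rule per column: depth
≥ 4 and a plurality allele (base, deletion, or insertion ≤ 50 bp) at
≥ 70% that differs from the reference; ties keep the reference. These
consensus thresholds are conservative defaults chosen to avoid
oscillation, as no canonical values exist. Edits inside protected
intervals — by default the poly(GC) runs of more than 10 G/C bases — are
recorded as `deferred_polygc` and not applied. Rounds remap and repeat
until quiescence (≤ 5 rounds), and the edit records replay exactly onto
the input to reproduce the output.

`curate_with_long_reads()` then resolves the protected intervals: every
long read (≥ 20 kb) spanning a padded protected window votes with its
aligned segment, and the plurality segment is applied only when supported
by **more than 5** reads (≥ 6); weaker suggestions are recorded as
`rejected_low_support` and the region is listed as unresolved. The
segment vote, rather than a per-column vote, is what a human curator does
when eyeballing a pileup: with indel-dominant errors, per-column
insertion evidence fragments across co-optimal placements and can fail to
reach the support threshold even when every read carries the correction.

## Assembly comparison and variant classification

`anchor_synteny()` chains unique shared 21-mers (≤ 4 occurrences per
genome) into co-oriented blocks, splitting at diagonal jumps > 32 bp and
at anchor gaps > 5 kb, then re-bridges consecutive blocks whose gap
contents align at ≥ 95% identity — this is how the anchor-free interior
of a 163-kb rDNA array rejoins its flanks instead of surfacing as a fake
substitution block. Inverted chains are kept separately as inversion
evidence, not as syntenic regions. Whole-genome identity is the
length-weighted mean identity over regions, computed by banded alignment
with exact-match short-circuit.

`call_svs()` types the gaps between adjacent blocks. Indel sizes come
from the *diagonal jump* between blocks, not the blurred block
boundaries, so a 14,090-bp collapse is reported at exactly 14,090 bp even
when repeats obscure the breakpoints. An inversion requires an inverted
chain covering the gap in *both* genomes with conserved gap size — a
one-sided inverted match is just homology to another inverted repeat
copy. Variants under 50 bp are counted as small indels rather than SVs; no
canonical boundary between the two exists, and 50 bp is this package's
line.

`classify_svs()` applies the evidence table in order: inversion flanked
by an inverted-repeat pair ≥ 1.5 kb → `mat_switch`; a-only content with
long-read junction support on both breakpoints and overlap with repeat
annotation (duplicated segment, LTR element, tandem array) →
`candidate_misassembly_in_b`; a-only content with support and no repeat
overlap → `true_sv`; b-only content stays unclassified unless the
a-junction fails. Labels for genome `b` are explicitly *candidates*
because reads from only one strain are assumed; the confirmation the
original workflow performed by human curation is encoded as the
junction-support test.

`detect_mat_inversion()` finds inverted-repeat pairs by anchoring each
contig against its own reverse complement, then tests whether the region
between the repeats matches the second assembly forward (no switch) or
reverse-complemented within a small edit budget (switch).
`estimate_mat_switch_frequency()` lets each long read spanning an outer
flank/inverted-repeat junction (500 bp beyond the repeat on both sides)
vote for the orientation whose junction reference it matches with fewer
edits; frequency is minority votes over total votes with a binomial 95%
CI, and zero informative reads yield "no estimate". How the original
study counted its informative subreads is not documented; this spanning
definition is the package's own and is stated here for that reason.

# Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; 1-based conversion
  happens only when writing GFF3.
* Alignment uses unit costs (mismatch 1, gap 1), matching the
  gap-inclusive identity denominator used in reporting; traceback prefers
  match, then consolidates gaps.
* Thresholds printed as inequalities are encoded strictly: "more than 5
  reads" is ≥ 6, "more than 10 G or C" is run length ≥ 11. Poly(GC) is
  defined over the alphabet {G,C} (mixed runs qualify); a
  homopolymer-only mode exists because the ambiguity is real.
* Degenerate inputs return empty-but-typed results (no arrays found,
  zero-row feature frames) or explicit errors (window larger than half a
  contig, junction outside the contig, infeasible generator configs), and
  estimators distinguish "no estimate" from zero.

# Problem sizes used by the test-suite

The acceptance tests run the detectors on twenty seeded 3 × 300-kb
genomes; polishing end-to-end uses ten 1 × 120-kb genomes at 50× short /
25× long coverage; variant classification uses twenty seeds at 12× long
coverage; copy-number estimation uses a 500-bp × 20 array so reads can
span it flank-to-flank under the read-length cap; stochastic mating-type
mixtures use 120 informative reads per seed. These sizes are the
package's choices for a desk-scale study system; every quantity the
documentation cites is recomputed by the tests or by
`scripts/acceptance.R`, never stored.

# Known limitations

* The toy mapper is not a production aligner: repeat interiors longer
  than a read receive no coverage (reads there are honestly ambiguous),
  and end extension is capped, so coverage fades deep inside the largest
  arrays. Real-data workflows should ingest external alignments instead.
* Uniform read sampling cannot produce reads that span a chromosome-end
  junction's outer flank (real molecules run past the telomere), so
  junction audits at the outermost edges of end-features are
  uninformative by construction.
* Inverted syntenic homology is reported as an inversion variant, not as
  a syntenic region.
* The generator's repeat units are random sequence; detectors are
  validated on geometry and divergence, not on family-specific sequence
  signals.
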
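# telosv

Genome-feature discovery and assembly curation for full-length
(telomere-to-telomere) yeast genomes.

Finishing a small eukaryotic genome is dominated by a handful of repeat
structures: telomeric tandem arrays `[ACCCCGCC]n` / `[GGCGGGGT]n` at the
chromosome ends, one very large rDNA tandem array (unit × copy number, with
copy number n = array span / unit length), LTR retrotransposons whose paired
LTRs are nearly identical, multi-kilobase **large duplicated segments
(LDSs)** sitting in subtelomeric regions at ~99.98% identity to their
paralogs, and a mating-type (MAT) locus whose ~19-kb cassette region inverts
between two ~2-kb inverted repeats. Each of these produces a characteristic
assembly artifact — collapsed duplications, dropped retroelements,
mis-polished poly(GC) tracts, and "structural variants" between two
assemblies that are really misassemblies or a MAT switch.

`telosv` provides, as tested R functions:

- **tandem-repeat arrays**: two-tier detection (per-position lag scanning
  for units ≤ 64 bp; k-mer spacing histograms for units up to 10 kb),
  rotation/strand-canonical units, copy numbers, purity; telomere calls at
  contig ends; copy-number estimation from spanning long reads (median of
  per-read unit-walk counts);
- **LTR retrotransposons**: paired-LTR discovery, `TCTTG`/`CAACA`
  target-site motif checks, six-frame ORF scans with a two-tier intactness
  model (structural vs coding), and copy-to-copy diffs with translated
  in-frame insertions;
- **subtelomeric duplicated segments**: window-pair anchoring, chaining,
  banded global alignment with exact mismatch/gap-column accounting, and
  telomere-like terminal-motif detection;
- **polish + curate**: iterative short-read pileup-consensus polishing with
  protection of poly(GC) runs (> 10 G/C bases), followed by long-read
  curation in which a correction must be confirmed by **more than 5**
  spanning long reads (> 20 kb); junction auditing requires breakpoints to
  be spanned by long reads;
- **assembly comparison**: anchor-based synteny, SV calling with exact
  indel sizes from diagonal jumps, classification into
  `true_sv` / `candidate_misassembly` / `mat_switch`, MAT-inversion
  detection, and MAT switch-frequency estimation from long-read votes with
  a binomial CI;
- **synthetic data**: a generator that plants every feature class with a
  ground-truth manifest, plus long-read (indel-dominant errors) and
  short-read (systematic poly(GC) errors) simulators — so the whole
  pipeline is validated against planted truth.

## Worked example

```r
library(telosv)

bg <- build_genome(synthetic_config(seed = 1))
bg$genome
#> Genome 'synthetic_truth': 3 contig(s), 900,000 bp total
#>   chr1  300,000 bp
#>   chr2  300,000 bp
#>   chr3  300,000 bp

call_telomeres(bg$genome)[1:3, c("contig","side","start","end","unit",
                                 "copy_number","purity")]
#>   contig   side  start    end     unit copy_number purity
#> 1   chr1 5prime      0    160 ACCCCGCC          20      1
#> 2   chr1 3prime 299840 300000 ACCCCGCC          20      1
#> 3   chr2 5prime      0    160 ACCCCGCC          20      1

segs <- detect_terminal_motif(find_duplicated_segments(bg$genome), bg$genome)
segs[, c("contig_a","start_a","contig_b","start_b","columns","n_mismatch",
         "n_gap_columns","identity","terminal_motif")]
#>   contig_a start_a contig_b start_b columns n_mismatch n_gap_columns  identity
#> 1     chr1     811     chr2  271215   27852          4             1 0.9998205
#> 2     chr1  296651     chr3     666    2500          3             1 0.9984000
#> 3     chr2     520     chr3  294314    5100          6             2 0.9984314
#>    terminal_motif
#> 1            none
#> 2 degenerate_unit
#> 3       full_unit
```

Every chromosome end carries its planted 20-copy telomere array (160 bp,
purity 1), and the three duplicated-segment pairs come back with their
exact planted divergence — the 27.85-kb pair differs from its paralog by
just 4 mismatches and one 1-bp gap (identity 1 − 5/27,852 ≈ 0.9998),
which is precisely why such segments get collapsed by ordinary assemblers.
The two smaller pairs end in telomere-like motifs (`[ACCCCGCC]4`,
`[ACCCGCC]3`), the signature of segments that were integrated at the 5'
ends of old telomeric regions by their 3' ends.

From here, `derive_alternate_assembly()` plants assembly defects
(collapsed LDS, dropped retroelement, MAT inversion, true variants),
`anchor_synteny()` + `call_svs()` + `classify_svs()` recover and label
them, and `polish_consensus()` + `curate_with_long_reads()` restore a
corrupted assembly to truth while the poly(GC) protection keeps systematic
short-read errors out.

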
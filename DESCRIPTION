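Package: telosv
Title: Genome-Feature Discovery and Assembly Curation for Full-Length Yeast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies the repeat structures that make telomere-to-telomere
    yeast assemblies hard to finish, and curates assemblies against long-read evidence.
    Includes tandem-repeat array discovery with copy-number estimation from assemblies
    and from spanning long reads, paired-LTR retrotransposon annotation with target-site
    motif checks and ORF-integrity tiers, discovery of near-identical large duplicated
    segments in subtelomeric regions, iterative short-read pileup polishing with
    protection of long poly(GC) tracts followed by long-read curation under explicit
    read-support thresholds, and anchor-based assembly-to-assembly synteny with
    structural-variant calling and evidence-based classification (true variant,
    collapsed-repeat misassembly, or inverted-repeat-mediated mating-type switch).
    A synthetic-genome generator plants every feature class with a ground-truth
    manifest and simulates long reads with indel-dominant errors and short reads
    with systematic poly(GC) errors, so every detector can be validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
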
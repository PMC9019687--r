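test_that("build_genome is a pure function of config and seed", {
  cfg <- small_config(seed = 21)
  a <- build_genome(cfg)
  b <- build_genome(cfg)
  expect_identical(a$genome$contigs, b$genome$contigs)
  expect_identical(a$manifest$features, b$manifest$features)
  # a different seed produces a different genome
  c2 <- build_genome(small_config(seed = 22))
  expect_false(identical(a$genome$contigs, c2$genome$contigs))
})

test_that("planted features have the configured geometry", {
  bg <- default_build()
  g <- bg$genome
  f <- bg$manifest$features
  # telomere arrays: 8 x 20 = 160 bp at position 0 and at the terminus
  tel <- f[f$type == "telomere", ]
  expect_equal(nrow(tel), 6L)
  expect_true(all(tel$end - tel$start == 160L))
  t5 <- tel[tel$side == "5prime", ]
  expect_true(all(t5$start == 0L))
  t3 <- tel[tel$side == "3prime", ]
  expect_true(all(t3$end == 300000L))
  for (i in seq_len(nrow(t5))) {
    expect_equal(substr(g$contigs[[t5$contig[i]]], 1, 160),
                 strrep("ACCCCGCC", 20))
  }
  for (i in seq_len(nrow(t3))) {
    expect_equal(substr(g$contigs[[t3$contig[i]]], 299841, 300000),
                 strrep("GGCGGGGT", 20))
  }
  # one rDNA array of 20 x 2 kb on one chromosome
  rd <- f[f$type == "rdna_array", ]
  expect_equal(nrow(rd), 1L)
  expect_equal(rd$end - rd$start, 40000L)
  # all intervals within bounds; one record per planted feature id
  expect_true(all(f$start >= 0 & f$end <= nchar(g$contigs)[f$contig]))
  expect_false(anyDuplicated(f$id) > 0)
  # LDS pair divergence exactly as configured
  lds <- f[f$type == "lds_copy", ]
  expect_equal(sort(unique(lds$pair_id)), c("LDS1", "LDS2", "LDS3"))
  l1 <- lds[lds$pair_id == "LDS1", ]
  expect_equal(unique(l1$n_mismatch), 4L)
  expect_equal(unique(l1$n_gap), 1L)
  expect_equal(l1$end - l1$start, c(27850L, 27849L))  # 1-bp gap in copy B
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(lds_specs = list(
    list(length = 100000L, n_mismatch = 1L, n_gap = 0L,
         terminal_motif = "none"))), "chrom_length/4")
  expect_error(synthetic_config(polygc_tracts = list(
    list(base = "G", len = 10L))), "> 10")
  expect_error(
    build_genome(synthetic_config(
      n_chromosomes = 1L, chrom_length = 50000L,
      lds_specs = list(list(length = 5000L, n_mismatch = 1L, n_gap = 0L,
                            terminal_motif = "none")))),
    "infeasible")
})

test_that("derive_alternate_assembly applies labelled defects locally", {
  bg <- default_build()
  g <- bg$genome
  alt <- derive_alternate_assembly(g, bg$manifest, list(
    list(collapse_lds = "LDS1", drop_bp = 14090),
    list(invert_mat = TRUE),
    list(true_sv = list(mode = "insert", length = 3000))), seed = 5)
  tr <- alt$truth
  expect_setequal(tr$label, c("assembly_error", "mat_switch", "true_sv"))
  expect_equal(tr$size[tr$kind == "collapsed_lds"], 14090L)
  expect_equal(tr$size[tr$kind == "insertion_in_b"], 3000L)
  # length bookkeeping
  dl <- genome_length(g) - genome_length(alt$genome)
  expect_equal(dl, 14090L - 3000L)
  # the inverted region is the reverse complement of the original
  m <- bg$manifest$features[bg$manifest$features$type == "mat_locus", ]
  inv_a <- substr(g$contigs[[m$contig]], m$inv_start + 1, m$inv_end)
  # account for coordinate shifts from any defect upstream on the contig
  up <- tr[tr$contig == m$contig & tr$start < m$inv_start &
             tr$kind != "mat_inversion", , drop = FALSE]
  shift <- sum(ifelse(up$kind == "insertion_in_b", -up$size, up$size))
  inv_b <- substr(alt$genome$contigs[[m$contig]], m$inv_start + 1 - shift,
                  m$inv_end - shift)
  expect_equal(inv_b, revcomp(inv_a))
  # untouched contigs are identical
  untouched <- setdiff(names(g$contigs), tr$contig)
  for (nm in untouched) {
    expect_identical(alt$genome$contigs[[nm]], g$contigs[[nm]])
  }
  expect_error(derive_alternate_assembly(g, bg$manifest,
                                         list(list(drop_ltr_rt = "nope"))),
               "unknown defect target")
})

test_that("long-read simulation honours coverage, errors and determinism", {
  bg <- build_genome(small_config(seed = 31))
  g <- bg$genome
  # zero error rates: every read is an exact substring of genome or rc
  lr0 <- simulate_long_reads(g, mean_len = 8000, len_sd = 1500,
                             coverage = 3, sub_rate = 0, ins_rate = 0,
                             del_rate = 0, seed = 1)
  s <- g$contigs[["chr1"]]
  for (i in seq_along(lr0$seqs)) {
    tr <- lr0$truth[i, ]
    expected <- substr(s, tr$start + 1, tr$end)
    if (tr$strand == "-") expected <- revcomp(expected)
    expect_identical(unname(lr0$seqs[[i]]), expected)
  }
  # coverage within 10% of target
  lr <- simulate_long_reads(g, coverage = 30, seed = 2)
  ratio <- sum(nchar(lr$seqs)) / genome_length(g)
  expect_lt(abs(ratio - 30) / 30, 0.1)
  # no read spans a whole chromosome
  expect_true(all(nchar(lr$seqs) <= nchar(s) / 3 + 1))
  # byte-identical FASTQ across runs with the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(simulate_long_reads(g, coverage = 2, seed = 9), f1)
  write_fastq(simulate_long_reads(g, coverage = 2, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("short-read simulation plants systematic poly(GC) errors only", {
  # genome without poly(GC) tracts: substitution-only noise
  set.seed(5)
  plain <- genome(c(chr1 = gsub("[GC]{11,}", "ATATATATATAT",
                                rand_dna(30000))))
  sr <- simulate_short_reads(plain, coverage = 4, sub_rate = 0,
                             polygc_error = list(run_min = 11,
                                                 error_prob = 1,
                                                 mode = "shrink"),
                             seed = 3)
  for (i in seq_along(sr$seqs)) {
    tr <- sr$truth[i, ]
    expected <- substr(plain$contigs[["chr1"]], tr$start + 1, tr$end)
    if (tr$strand == "-") expected <- revcomp(expected)
    expect_identical(unname(sr$seqs[[i]]), expected)
  }
  # planted 14-G run with error_prob 1, shrink: every fully covering read
  # reports 13 Gs
  g14 <- genome(c(chr1 = paste0(rand_dna(2000, seed = 6), "AT",
                                strrep("G", 14), "TA", rand_dna(2000))))
  runs <- detect_polygc(g14)
  run <- runs[which.max(runs$end - runs$start), ]
  expect_equal(run$end - run$start, 14L)
  sr2 <- simulate_short_reads(g14, coverage = 30, sub_rate = 0,
                              polygc_error = list(run_min = 11,
                                                  error_prob = 1,
                                                  mode = "shrink"),
                              seed = 4)
  cover <- sr2$truth$start <= run$start & sr2$truth$end >= run$end
  expect_gt(sum(cover), 5)
  for (i in which(cover)) {
    q <- sr2$seqs[[i]]
    if (sr2$truth$strand[i] == "-") q <- revcomp(q)
    gr <- regmatches(q, gregexpr("G{10,}", q))[[1]]
    expect_equal(max(nchar(gr)), 13L)
  }
})

test_that("paired short-read mode emits proper mate pairs", {
  bg <- build_genome(small_config(seed = 41))
  sr <- simulate_short_reads(bg$genome, coverage = 2, paired = TRUE,
                             insert_size = 400, sub_rate = 0,
                             polygc_error = list(run_min = 11,
                                                 error_prob = 0,
                                                 mode = "shrink"),
                             seed = 1)
  expect_equal(length(sr$seqs) %% 2L, 0L)
  tr <- sr$truth
  m1 <- tr[seq(1, nrow(tr), 2), ]
  m2 <- tr[seq(2, nrow(tr), 2), ]
  expect_true(all(m2$start - m1$start == 400 - 150))
  expect_true(all(m1$strand == "+" & m2$strand == "-"))
})

test_that("a marked CDS accepts a 5-bp insertion that one alignment reveals", {
  bg <- build_genome(small_config(seed = 51))
  g <- bg$genome
  cds <- bg$manifest$features[bg$manifest$features$type == "marked_cds", ]
  expect_equal(cds$end - cds$start, 672L)
  # insert GAAGT after base 31 of the CDS (frame-shift knockout emulation)
  g2 <- apply_insertion(g, cds$contig, cds$start + 31L, "GAAGT")
  expect_equal(genome_length(g2) - genome_length(g), 5L)
  al <- telosv:::cpp_banded_align(g$contigs[[cds$contig]],
                                 g2$contigs[[cds$contig]], 16L)
  ops <- telosv:::parse_cigar(al$cigar)
  ins <- ops[ops$op == "I", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$len, 5L)
  expect_equal(al$edit, 5L)
})
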
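test_that("poly(GC) region detection applies the more-than-10 rule", {
  g <- genome(c(c1 = paste0("AAA", strrep("G", 11), "AAA"),
                c2 = paste0("AAA", strrep("G", 10), "AAA"),
                c3 = paste0("AA", strrep("GC", 6), "AA"),
                c4 = paste0("AA", strrep("G", 12), "A", strrep("C", 13),
                            "AA")))
  runs <- detect_polygc(g, run_min = 11)
  expect_equal(runs$contig, c("c1", "c3", "c4", "c4"))
  expect_equal(runs$end - runs$start, c(11L, 12L, 12L, 13L))
  # pure-homopolymer mode excludes the mixed G/C run
  hp <- detect_polygc(g, run_min = 11, homopolymer_only = TRUE)
  expect_false("c3" %in% hp$contig)
  expect_true(all(c("c1", "c4") %in% hp$contig))
})

test_that("the toy mapper places error-free reads exactly and deterministically", {
  bg <- build_genome(small_config(seed = 71))
  g <- bg$genome
  sr <- simulate_short_reads(g, coverage = 3, sub_rate = 0,
                             polygc_error = list(run_min = 11,
                                                 error_prob = 0,
                                                 mode = "shrink"),
                             seed = 1)
  al <- map_reads(g, sr, "short")
  m <- al$aln$status == "mapped"
  expect_gt(mean(m), 0.5)          # repeat-interior reads stay unmapped
  expect_true(all(al$aln$edit[m] == 0))
  expect_equal(al$aln$ref_start[m], sr$truth$start[m])
  expect_equal(al$aln$strand[m], sr$truth$strand[m])
  # ambiguous placements are reported, not guessed
  expect_true(any(al$aln$status %in% c("ambiguous", "no_seed")))
  al2 <- map_reads(g, sr, "short")
  expect_identical(al$aln, al2$aln)
})

test_that("polishing is idempotent on a correct assembly", {
  bg <- build_genome(small_config(seed = 72))
  g <- bg$genome
  sr <- simulate_short_reads(g, coverage = 40, sub_rate = 0,
                             polygc_error = list(run_min = 11,
                                                 error_prob = 0,
                                                 mode = "shrink"),
                             seed = 2)
  al <- map_reads(g, sr, "short")
  pol <- polish_consensus(g, al, curation_policy(), protected = NULL)
  expect_equal(sum(pol$records$status == "applied"), 0L)
  expect_identical(pol$genome$contigs, g$contigs)
})

test_that("polishing reverts planted substitutions and replays exactly", {
  bg <- build_genome(small_config(seed = 73))
  g <- bg$genome
  corrupt <- corrupt_substitutions(g, bg$manifest, 25L, seed = 3)
  sr <- simulate_short_reads(g, coverage = 50, seed = 4)
  al <- map_reads(corrupt, sr, "short")
  prot <- detect_polygc(corrupt)
  pol <- polish_consensus(corrupt, al, curation_policy(), prot)
  expect_identical(pol$genome$contigs, g$contigs)
  applied <- pol$records[pol$records$status == "applied", ]
  expect_equal(nrow(applied), 25L)
  expect_true(all(applied$kind == "sub"))
  # applied-edit count is non-increasing across rounds
  per_round <- table(factor(applied$round, levels = seq_len(pol$rounds)))
  expect_true(all(diff(as.integer(per_round)) <= 0))
  # replaying the records on the input reproduces the output
  expect_identical(replay_edits(corrupt, pol$records)$contigs,
                   pol$genome$contigs)
})

test_that("protection defers poly(GC) edits that naive polishing would apply", {
  bg <- build_genome(small_config(seed = 74))
  g <- bg$genome
  # reads carry fully systematic shrink errors in every long G/C run
  sr <- simulate_short_reads(g, coverage = 50,
                             polygc_error = list(run_min = 11,
                                                 error_prob = 1,
                                                 mode = "shrink"),
                             seed = 5)
  runs <- detect_polygc(g)
  al <- map_reads(g, sr, "short")
  off <- polish_consensus(g, al, curation_policy(), protected = NULL)
  expect_gt(sum(off$records$status == "applied"), 0L)
  expect_false(identical(off$genome$contigs, g$contigs))
  # every corruption the unprotected run applied lies inside a run
  ap <- off$records[off$records$status == "applied", ]
  for (i in seq_len(nrow(ap))) {
    r <- runs[runs$contig == ap$contig[i], ]
    expect_true(any(ap$pos[i] >= r$start - 1 & ap$pos[i] < r$end))
  }
  on <- polish_consensus(g, map_reads(g, sr, "short"), curation_policy(),
                         protected = runs)
  expect_identical(on$genome$contigs, g$contigs)
  expect_gt(sum(on$records$status == "deferred_polygc"), 0L)
  expect_equal(sum(on$records$status == "applied"), 0L)
})

test_that("curation applies corrections at 6 supporting reads and not at 5", {
  set.seed(6)
  flank1 <- rand_dna(3000)
  flank2 <- rand_dna(3000)
  truth <- paste0(flank1, strrep("G", 14), flank2)
  shrunk <- paste0(flank1, strrep("G", 13), flank2)
  ga <- genome(c(chr1 = shrunk))
  prot <- detect_polygc(ga)
  pol <- curation_policy(long_read_min = 1000L)
  mk_reads <- function(n) {
    read_set(setNames(rep(substr(truth, 500, 5600), n),
                      sprintf("r%02d", seq_len(n))))
  }
  # exactly 5 spanning reads: suggestion rejected, region unresolved
  al5 <- map_reads(ga, mk_reads(5), "long")
  cur5 <- curate_with_long_reads(ga, al5, prot, pol)
  expect_equal(sum(cur5$records$status == "applied"), 0L)
  expect_gte(sum(cur5$records$status == "rejected_low_support"), 1L)
  expect_gte(nrow(cur5$unresolved), 1L)
  expect_identical(cur5$genome$contigs[["chr1"]], shrunk)
  # six reads: corrected
  al6 <- map_reads(ga, mk_reads(6), "long")
  cur6 <- curate_with_long_reads(ga, al6, prot, pol)
  applied <- cur6$records[cur6$records$status == "applied", ]
  expect_equal(nrow(applied), 1L)
  expect_gte(applied$support, 6L)
  expect_identical(cur6$genome$contigs[["chr1"]], truth)
  # an already-correct protected interval receives no edit
  alT <- map_reads(genome(c(chr1 = truth)), mk_reads(10), "long")
  curT <- curate_with_long_reads(genome(c(chr1 = truth)), alT,
                                 detect_polygc(genome(c(chr1 = truth))),
                                 pol)
  expect_equal(nrow(curT$records), 0L)
})

test_that("audit_junctions reports pass/fail per feature junction", {
  bg <- build_genome(small_config(seed = 75))
  g <- bg$genome
  f <- bg$manifest$features
  lr <- simulate_long_reads(g, coverage = 25, seed = 7)
  al <- map_reads(g, lr, "long")
  lds <- f[f$type == "lds_copy", ][1, ]
  ltr <- f[f$type == "ltr_rt", ][1, ]
  jn <- data.frame(id = c("lds_end", "ltr_start", "ltr_end"),
                   contig = c(lds$contig, ltr$contig, ltr$contig),
                   position = c(lds$end, ltr$start, ltr$end),
                   stringsAsFactors = FALSE)
  rep <- audit_junctions(g, jn, al)
  expect_true(all(rep$pass))
  # empty feature list -> empty report
  rep0 <- audit_junctions(g, jn[0, ], al)
  expect_equal(nrow(rep0), 0L)
})

test_that("curation policy enforces the printed thresholds", {
  expect_error(curation_policy(min_confirm_reads = 5L))
  expect_error(curation_policy(polygc_run_min = 10L))
  p <- curation_policy()
  expect_equal(p$min_confirm_reads, 6L)
  expect_equal(p$polygc_run_min, 11L)
  expect_equal(p$long_read_min, 20000L)
  expect_equal(p$lds_read_min, 30000L)
})
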
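# SV-segmentation oracle on toy genomes: full dynamic-programming global
# alignment (independent aligner) segmented into indel blocks >= min_sv
oracle_sv_segments <- function(sa, sb, min_sv = 50L) {
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2),
    gapOpening = -10, gapExtension = -1)
  # deletions relative to the pattern = content present only in sb
  insb <- Biostrings::deletion(pa)[[1]]   # gaps inserted into pattern
  ina <- Biostrings::insertion(pa)[[1]]   # gaps inserted into subject
  list(
    only_in_a = data.frame(
      width = BiocGenerics::width(ina)[BiocGenerics::width(ina) >= min_sv]),
    only_in_b = data.frame(
      width = BiocGenerics::width(insb)[BiocGenerics::width(insb) >=
                                          min_sv]))
}

test_that("synteny of a genome with itself is total and exact", {
  bg <- build_genome(small_config(seed = 81))
  g <- bg$genome
  syn <- anchor_synteny(g, g)
  expect_equal(syn$weighted_identity, 1)
  expect_gt(syn$coverage_a, 0.99)
  expect_gt(syn$coverage_b, 0.99)
  svs <- call_svs(syn, g, g)
  expect_equal(nrow(svs), 0L)
})

test_that("unrelated genomes share almost no synteny", {
  g1 <- genome(c(c1 = rand_dna(50000, seed = 1)))
  g2 <- genome(c(c1 = rand_dna(50000, seed = 2)))
  expect_warning(syn <- anchor_synteny(g1, g2), "no shared")
  expect_lt(syn$coverage_a, 0.05)
})

test_that("whole-genome identity recovers a 0.5% substitution rate", {
  bg <- build_genome(small_config(seed = 82))
  g <- bg$genome
  gm <- mutate_genome(g, sub_rate = 0.005, seed = 3)
  syn <- anchor_synteny(g, gm)
  expect_lt(abs(syn$weighted_identity - 0.995), 0.001)
  expect_gt(syn$coverage_a, 0.95)
})

test_that("planted indel variants are called with exact sizes", {
  bg <- build_genome(small_config(seed = 83, chrom_length = 200000L))
  g <- bg$genome
  alt <- derive_alternate_assembly(g, bg$manifest, list(
    list(true_sv = list(mode = "delete", length = 3000)),
    list(true_sv = list(mode = "insert", length = 1200))), seed = 4)
  syn <- anchor_synteny(g, alt$genome, align = FALSE)
  svs <- call_svs(syn, g, alt$genome)
  expect_equal(nrow(svs), 2L)
  del <- svs[svs$sv_type == "deletion", ]
  ins <- svs[svs$sv_type == "insertion_in_b", ]
  expect_equal(del$size, 3000L)
  expect_equal(ins$size, 1200L)
  tr <- alt$truth
  tdel <- tr[tr$kind == "deletion_in_b", ]
  expect_equal(del$contig_a, tdel$contig)
  expect_lte(abs(del$start_a - tdel$start), 25L)
})

test_that("toy-genome variant calls match a full-alignment oracle", {
  set.seed(91)
  base <- rand_dna(18000)
  # b lacks a 300-bp block and gains a 180-bp block
  b <- paste0(substr(base, 1, 5000), substr(base, 5301, 12000),
              rand_dna(180), substr(base, 12001, 18000))
  ga <- genome(c(chr = base))
  gb <- genome(c(chr = b))
  syn <- anchor_synteny(ga, gb, align = FALSE)
  svs <- call_svs(syn, ga, gb, min_sv = 50L)
  orc <- oracle_sv_segments(base, b, min_sv = 50L)
  expect_equal(sort(svs$size[svs$sv_type == "deletion"]),
               sort(orc$only_in_a$width))
  expect_equal(sort(svs$size[svs$sv_type == "insertion_in_b"]),
               sort(orc$only_in_b$width))
  expect_equal(nrow(svs), 2L)
})

test_that("defect classification matches the planted truth labels", {
  bg <- default_build()
  g <- bg$genome
  alt <- derive_alternate_assembly(g, bg$manifest, list(
    list(collapse_lds = "LDS1", drop_bp = 14090),
    list(drop_ltr_rt = "ltr_rt1"),
    list(invert_mat = TRUE),
    list(true_sv = list(mode = "delete", length = 3000))), seed = 5)
  b <- alt$genome
  syn <- anchor_synteny(g, b, align = FALSE)
  svs <- call_svs(syn, g, b)
  expect_equal(nrow(svs), 4L)
  expect_equal(svs$size[svs$sv_type == "inversion"], 19000L)
  expect_true(14090 %in% svs$size)
  lr <- simulate_long_reads(g, coverage = 12, seed = 6)
  al <- map_reads(g, lr, "long")
  cl <- classify_svs(svs, g, b, al,
                     repeats_a = list(ltr = find_ltr_pairs(g),
                                      lds = find_duplicated_segments(g)))
  expect_equal(cl$classification[cl$sv_type == "inversion"], "mat_switch")
  expect_true(cl$ir_flanked[cl$sv_type == "inversion"])
  expect_equal(cl$classification[cl$size == 14090],
               "candidate_misassembly_in_b")
  expect_equal(cl$repeat_kind[cl$size == 14090], "LDS")
  expect_equal(cl$classification[cl$size == 3000], "true_sv")
  drop_sz <- cl$size[cl$repeat_kind == "LTR_rt"]
  expect_equal(cl$classification[cl$repeat_kind == "LTR_rt"],
               "candidate_misassembly_in_b")
  expect_gt(drop_sz, 4000)
})

test_that("mating-type inversion detection requires real inverted context", {
  bg <- default_build()
  g <- bg$genome
  alt <- derive_alternate_assembly(g, bg$manifest,
                                   list(list(invert_mat = TRUE)), seed = 7)
  mat <- detect_mat_inversion(g, alt$genome)
  expect_s3_class(data.frame(x = 1), "data.frame")  # anchor sanity
  expect_false(is.null(mat))
  m <- bg$manifest$features[bg$manifest$features$type == "mat_locus", ]
  expect_equal(mat$contig, m$contig)
  expect_lte(abs(mat$ir_length - 2000L), 5L)
  expect_lte(abs((mat$invertible[2] - mat$invertible[1]) - 19000L), 5L)
  expect_equal(mat$orientation_in_a, "alpha")
  expect_equal(mat$orientation_in_b, "a")
  # identical genomes: none
  expect_null(detect_mat_inversion(g, g))
  # inverted repeats below the length threshold are not called
  expect_null(detect_mat_inversion(g, alt$genome, min_ir = 3000L))
})

test_that("switch frequency is exact on planted mixtures", {
  bg <- default_build()
  g <- bg$genome
  alt <- derive_alternate_assembly(g, bg$manifest,
                                   list(list(invert_mat = TRUE)), seed = 8)
  mat <- detect_mat_inversion(g, alt$genome)
  s <- g$contigs[[mat$contig]]
  w0 <- mat$ir1[1] - 2000L
  w1 <- mat$ir1[2] + 2000L
  alpha_read <- substr(s, w0 + 1, w1)
  a_read <- substr(alt$genome$contigs[[mat$contig]], w0 + 1, w1)
  pol <- curation_policy(long_read_min = 1000L)
  reads <- read_set(setNames(c(rep(alpha_read, 263), a_read),
                             sprintf("r%03d", 1:264)))
  est <- estimate_mat_switch_frequency(reads, mat, g, pol)
  expect_equal(est$per_read_votes$alpha, 263L)
  expect_equal(est$per_read_votes$a, 1L)
  expect_equal(est$switch_frequency, 1 / 264)
  # all reads one orientation: frequency zero
  est0 <- estimate_mat_switch_frequency(
    read_set(setNames(rep(alpha_read, 20), sprintf("s%02d", 1:20))),
    mat, g, pol)
  expect_equal(est0$switch_frequency, 0)
  # reads that span nothing informative: no estimate
  estN <- estimate_mat_switch_frequency(
    read_set(c(x = rand_dna(5000, seed = 10))), mat, g, pol)
  expect_true(is.na(estN$switch_frequency))
})

test_that("stochastic mixtures are recovered within the binomial interval", {
  bg <- default_build()
  g <- bg$genome
  alt <- derive_alternate_assembly(g, bg$manifest,
                                   list(list(invert_mat = TRUE)), seed = 9)
  mat <- detect_mat_inversion(g, alt$genome)
  s <- g$contigs[[mat$contig]]
  w0 <- mat$ir1[1] - 1500L
  w1 <- mat$ir1[2] + 1500L
  alpha_read <- substr(s, w0 + 1, w1)
  a_read <- substr(alt$genome$contigs[[mat$contig]], w0 + 1, w1)
  pol <- curation_policy(long_read_min = 1000L)
  set.seed(11)
  p <- 0.05
  n <- 200L
  sw <- runif(n) < p
  reads <- read_set(setNames(ifelse(sw, a_read, alpha_read),
                             sprintf("m%03d", seq_len(n))))
  est <- estimate_mat_switch_frequency(reads, mat, g, pol)
  expect_equal(est$per_read_votes$a, sum(sw))
  expect_true(est$ci95[1] <= p && p <= est$ci95[2])
})
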
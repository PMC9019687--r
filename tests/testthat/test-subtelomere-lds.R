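test_that("end windows are extracted and validated", {
  g <- genome(c(chrA = rand_dna(300000, seed = 1)))
  w <- extract_end_windows(g, 50000)
  expect_equal(w$start, c(0L, 250000L))
  expect_equal(w$end, c(50000L, 300000L))
  expect_equal(w$side, c("5prime", "3prime"))
  expect_error(extract_end_windows(g, 200000), "half")
})

test_that("planted duplicated segments are recovered with exact divergence", {
  bg <- default_build()
  g <- bg$genome
  f <- bg$manifest$features
  truth <- f[f$type == "lds_copy", ]
  segs <- detect_terminal_motif(find_duplicated_segments(g), g)
  expect_equal(nrow(segs), 3L)
  for (pid in c("LDS1", "LDS2", "LDS3")) {
    tp <- truth[truth$pair_id == pid, ]
    hit <- segs[segs$n_mismatch == tp$n_mismatch[1] &
                  segs$n_gap_columns == tp$n_gap[1], , drop = FALSE]
    hit <- hit[abs(hit$columns - (tp$end[1] - tp$start[1])) < 10, ,
               drop = FALSE]
    expect_equal(nrow(hit), 1L)
    # boundary error within 5 bp on all four coordinates
    tA <- tp[tp$copy == "A", ]; tB <- tp[tp$copy == "B", ]
    got <- c(hit$start_a, hit$end_a, hit$start_b, hit$end_b)
    want1 <- c(tA$start, tA$end, tB$start, tB$end)
    want2 <- c(tB$start, tB$end, tA$start, tA$end)
    expect_true(max(abs(got - want1)) <= 5 || max(abs(got - want2)) <= 5)
    expect_equal(hit$orientation, "same")
    expect_equal(hit$terminal_motif, tp$terminal_motif[1])
    if (tp$terminal_motif[1] != "none") {
      expect_equal(hit$terminal_motif_copies, tp$motif_copies[1])
    }
    # identity arithmetic: 1 - (mm + gaps) / columns
    expect_equal(hit$identity,
                 1 - (hit$n_mismatch + hit$n_gap_columns) / hit$columns)
  }
  # the big pair reproduces the 4-mismatch + one 1-bp-gap arithmetic
  l1 <- segs[segs$columns > 20000, ]
  expect_equal(l1$n_mismatch, 4L)
  expect_equal(l1$n_gap_columns, 1L)
  expect_equal(l1$columns, 27851L)
  expect_equal(l1$identity, 1 - 5 / 27851)
})

test_that("unrelated windows yield no segments and order does not matter", {
  g <- genome(c(c1 = rand_dna(30000, seed = 4), c2 = rand_dna(30000)))
  w <- extract_end_windows(g, 10000)
  expect_equal(nrow(find_duplicated_segments(g, w, min_len = 1000)), 0L)

  bg <- default_build()
  w2 <- extract_end_windows(bg$genome)
  s1 <- find_duplicated_segments(bg$genome, w2)
  s2 <- find_duplicated_segments(bg$genome, w2[rev(seq_len(nrow(w2))), ])
  cols <- c("contig_a", "start_a", "end_a", "contig_b", "start_b", "end_b",
            "n_mismatch", "n_gap_columns")
  expect_equal(s1[do.call(order, s1[cols]), cols],
               s2[do.call(order, s2[cols]), cols],
               ignore_attr = TRUE)
})

test_that("divergence counts match a full dynamic-programming oracle", {
  # small planted pair aligned with an independent full-DP aligner
  set.seed(44)
  body <- rand_dna(4000)
  copyB <- body
  pos <- sample(200:3800, 6)
  for (p in pos[1:5]) {
    old <- substr(copyB, p, p)
    substr(copyB, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  copyB <- paste0(substr(copyB, 1, pos[6]), substr(copyB, pos[6] + 2, 4000))
  g <- genome(c(w1 = paste0(rand_dna(500), body, rand_dna(500)),
                w2 = paste0(rand_dna(500), copyB, rand_dna(500))))
  w <- data.frame(contig = c("w1", "w2"), start = 0L,
                  end = nchar(g$contigs), side = "5prime",
                  stringsAsFactors = FALSE)
  segs <- find_duplicated_segments(g, w, min_len = 2000, min_identity = 0.99)
  expect_equal(nrow(segs), 1L)
  sa <- substr(g$contigs[["w1"]], segs$start_a + 1, segs$end_a)
  sb <- substr(g$contigs[["w2"]], segs$start_b + 1, segs$end_b)
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 0, mismatch = -1),
    gapOpening = 0, gapExtension = 1)
  oracle_mm <- Biostrings::nmismatch(pa)
  oracle_gap <- sum(Biostrings::nindel(pa)@insertion[, "WidthSum"]) +
    sum(Biostrings::nindel(pa)@deletion[, "WidthSum"])
  expect_equal(segs$n_mismatch, oracle_mm)
  expect_equal(segs$n_gap_columns, oracle_gap)
  expect_equal(segs$n_mismatch, 5L)
  expect_equal(segs$n_gap_columns, 1L)
})

test_that("terminal motif calls enforce the more-than-two-copies rule", {
  set.seed(55)
  mk <- function(motif_run) {
    body <- paste0(rand_dna(3000), "T", motif_run)
    g <- genome(c(x = paste0(rand_dna(300), body, rand_dna(400)),
                  y = paste0(rand_dna(350), body, rand_dna(350))))
    w <- data.frame(contig = c("x", "y"), start = 0L,
                    end = nchar(g$contigs), side = "5prime",
                    stringsAsFactors = FALSE)
    segs <- find_duplicated_segments(g, w, min_len = 2000)
    detect_terminal_motif(segs, g)
  }
  full4 <- mk(strrep("ACCCCGCC", 4))
  expect_equal(full4$terminal_motif, "full_unit")
  expect_equal(full4$terminal_motif_copies, 4)
  deg3 <- mk(strrep("ACCCGCC", 3))
  expect_equal(deg3$terminal_motif, "degenerate_unit")
  expect_equal(deg3$terminal_motif_copies, 3)
  only2 <- mk(strrep("ACCCCGCC", 2))
  expect_equal(only2$terminal_motif, "none")
})

test_that("junction support counts spanning long reads honestly", {
  bg <- build_genome(small_config(seed = 61))
  g <- bg$genome
  lds <- bg$manifest$features[bg$manifest$features$type == "lds_copy", ][1, ]
  lr <- simulate_long_reads(g, mean_len = 25000, coverage = 30,
                            sub_rate = 0, ins_rate = 0, del_rate = 0,
                            seed = 2)
  al <- map_reads(g, lr, "long")
  pol <- curation_policy()
  # interior-facing boundary junction of the duplicated segment: spanned
  r1 <- verify_junction_support(list(contig = lds$contig,
                                     position = lds$end),
                                al, pol, assembly = g)
  expect_true(r1$pass)
  expect_gte(r1$n_spanning, 1L)
  # a fabricated chimeric assembly junction gets no spanning read
  chim <- genome(c(chr1 = paste0(substr(g$contigs[[1]], 1, 40000),
                                 rand_dna(30000, seed = 9),
                                 substr(g$contigs[[1]], 40001, 80000))))
  al2 <- map_reads(chim, lr, "long")
  r2 <- verify_junction_support(list(contig = "chr1", position = 40000L),
                                al2, pol, assembly = chim)
  expect_equal(r2$n_spanning, 0L)
  expect_false(r2$pass)
  # flank larger than any read cannot be spanned
  r3 <- verify_junction_support(list(contig = lds$contig,
                                     position = lds$start,
                                     flank = 60000L),
                                al, pol, assembly = g)
  expect_equal(r3$n_spanning, 0L)
  expect_false(r3$pass)
  expect_error(verify_junction_support(
    list(contig = lds$contig, position = 10 * genome_length(g)), al, pol,
    assembly = g), "outside")
})
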
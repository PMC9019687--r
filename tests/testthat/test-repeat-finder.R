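test_that("canonical_unit closes over rotation and strand", {
  expect_equal(canonical_unit("GGCGGGGT"), canonical_unit("ACCCCGCC"))
  expect_equal(canonical_unit("AAAA"), "AAAA")
  u <- "ACCCCGCC"
  rots <- vapply(0:7, function(i) {
    paste0(substr(u, i + 1, 8), substr(u, 1, i))
  }, character(1))
  canon <- unique(vapply(rots, canonical_unit, character(1)))
  expect_length(canon, 1L)
  expect_equal(canonical_unit(canon), canon)  # idempotent
})

test_that("pure planted arrays are recovered with exact geometry", {
  set.seed(17)
  s <- paste0(rand_dna(500), "T", strrep("ACCCCGCC", 20), "T", rand_dna(500))
  arr <- find_tandem_arrays(s)
  hit <- arr[arr$unit == canonical_unit("ACCCCGCC"), ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 501L)
  expect_equal(hit$end, 501L + 160L)
  expect_equal(hit$unit_length, 8L)
  expect_equal(hit$copy_number, 20.0)
  expect_equal(hit$purity, 1.0)
  # copy_number x unit_length within one unit of the interval length
  expect_true(all(abs(arr$copy_number * arr$unit_length -
                        (arr$end - arr$start)) < arr$unit_length))
})

test_that("large-period arrays (rDNA scale) are detected via k-mer spacing", {
  bg <- default_build()
  g <- bg$genome
  rd <- bg$manifest$features[bg$manifest$features$type == "rdna_array", ]
  arr <- find_tandem_arrays(g$contigs[[rd$contig]])
  big <- arr[arr$unit_length > 64, ]
  expect_equal(nrow(big), 1L)
  expect_equal(big$start, rd$start)
  expect_equal(big$end, rd$end)
  expect_equal(big$unit_length, 2000L)
  expect_equal(big$copy_number, 20.0)
  expect_equal(big$purity, 1.0)
})

test_that("tandem-array calls are strand invariant", {
  set.seed(23)
  s <- paste0(rand_dna(400), "T", strrep("ACCCCGCC", 12), "T", rand_dna(300),
              "G", strrep("CAGTA", 8), "T", rand_dna(200))
  a1 <- find_tandem_arrays(s)
  a2 <- find_tandem_arrays(revcomp(s))
  expect_equal(nrow(a1), nrow(a2))
  n <- nchar(s)
  mirrored <- data.frame(start = n - a2$end, end = n - a2$start,
                         unit = a2$unit, unit_length = a2$unit_length,
                         copy_number = a2$copy_number, purity = a2$purity)
  mirrored <- mirrored[order(mirrored$start), ]
  rownames(mirrored) <- NULL
  expect_equal(mirrored[, c("start", "end", "unit", "unit_length",
                            "copy_number", "purity")],
               a1[, c("start", "end", "unit", "unit_length",
                      "copy_number", "purity")])
})

test_that("small-sequence calls match the brute-force oracle", {
  set.seed(29)
  for (trial in 1:5) {
    s <- paste0(rand_dna(600), "C", strrep("GATTACA", 5), "T", rand_dna(400),
                "A", strrep("CCGTTAGCAAGT", 4), "A", rand_dna(300))
    orc <- oracle_tandem(s, 4L, 16L, 3)
    # drop oracle hits that are harmonics of a smaller reported period
    det <- find_tandem_arrays(s, min_unit = 4L, max_unit = 16L,
                              min_copies = 3, min_purity = 1)
    # boundary conventions may differ by a sub-half-unit partial copy
    for (i in seq_len(nrow(det))) {
      tol <- det$unit_length[i] %/% 2
      cover <- orc$start >= det$start[i] - tol &
        orc$end <= det$end[i] + tol
      expect_true(any(cover & orc$period %% det$unit_length[i] == 0),
                  info = sprintf("trial %d: detected array %d-%d p%d",
                                 trial, det$start[i], det$end[i],
                                 det$unit_length[i]))
    }
    # every oracle array at its fundamental period is detected
    fund <- orc[!duplicated(orc[, c("start", "end")]), ]
    for (i in seq_len(nrow(fund))) {
      tol <- fund$period[i] %/% 2
      cover <- det$start <= fund$start[i] + tol &
        det$end >= fund$end[i] - tol
      expect_true(any(cover),
                  info = sprintf("trial %d: oracle array %d-%d p%d missed",
                                 trial, fund$start[i], fund$end[i],
                                 fund$period[i]))
    }
  }
})

test_that("telomere calls find both ends exactly and skip missing ends", {
  bg <- default_build()
  g <- bg$genome
  tel <- call_telomeres(g)
  expect_equal(nrow(tel), 6L)
  expect_true(all(tel$length == 160L))
  expect_true(all(tel$copy_number == 20.0))
  expect_true(all(tel$unit == canonical_unit("ACCCCGCC")))
  expect_true(all(tel$start[tel$side == "5prime"] == 0L))
  expect_true(all(tel$end[tel$side == "3prime"] == 300000L))
  # genome with one end lacking a telomere
  g2 <- g
  g2$contigs[["chr1"]] <- substr(g2$contigs[["chr1"]], 200,
                                 nchar(g2$contigs[["chr1"]]))
  tel2 <- call_telomeres(g2)
  expect_false(any(tel2$contig == "chr1" & tel2$side == "5prime"))
  expect_true(any(tel2$contig == "chr1" & tel2$side == "3prime"))
})

test_that("telomere detector is symmetric under strand flip", {
  bg <- default_build()
  g <- bg$genome
  gr <- g
  for (nm in names(gr$contigs)) gr$contigs[[nm]] <- revcomp(gr$contigs[[nm]])
  t1 <- call_telomeres(g)
  t2 <- call_telomeres(gr)
  expect_equal(nrow(t1), nrow(t2))
  expect_equal(sort(t1$length), sort(t2$length))
  expect_equal(mean(t1$length[t1$side == "5prime"]),
               mean(t2$length[t2$side == "5prime"]))
})

test_that("copy number from spanning reads equals the planted count", {
  cfg <- small_config(seed = 9, chrom_length = 150000L,
                      rdna_unit_length = 500L)
  bg <- build_genome(cfg)
  g <- bg$genome
  r <- bg$manifest$features[bg$manifest$features$type == "rdna_array", ]
  s <- g$contigs[[r$contig]]
  flankL <- substr(s, r$start - 49, r$start)
  flankR <- substr(s, r$end + 1, r$end + 50)
  unit <- substr(s, r$start + 1, r$start + 500)
  # error-free reads
  lr0 <- simulate_long_reads(g, coverage = 10, sub_rate = 0, ins_rate = 0,
                             del_rate = 0, seed = 12)
  est0 <- estimate_copy_number_from_reads(lr0, unit, flankL, flankR)
  expect_equal(est0$median, 20)
  # default error rates: median exact, >= 90% of counts within +-2
  lr <- simulate_long_reads(g, coverage = 30, seed = 11)
  est <- estimate_copy_number_from_reads(lr, unit, flankL, flankR)
  expect_equal(est$median, 20)
  expect_gte(mean(abs(est$per_read_counts - 20) <= 2), 0.9)
  expect_gte(est$n_informative_reads, 5L)
  # reads too short to span: explicit no-estimate
  lrS <- simulate_long_reads(g, mean_len = 3000, len_sd = 100, coverage = 5,
                             seed = 13)
  estS <- estimate_copy_number_from_reads(lrS, unit, flankL, flankR,
                                          min_read_len = 1000)
  expect_true(is.na(estS$median))
  expect_equal(estS$n_informative_reads, 0L)
})
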
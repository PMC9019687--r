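# Synthetic miniature yeast-like genomes with planted ground truth:
# chromosome-end telomere arrays, one rDNA tandem array, intact and degraded
# LTR retrotransposons with target-site motif flanks, near-identical
# subtelomeric duplicated-segment pairs with telomere-like terminal motifs,
# a mating-type locus flanked by inverted repeats, poly(GC)/STR/low-complexity
# tracts, and read simulators with platform-specific error structure.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Configuration for the synthetic genome generator
#'
#' The defaults describe the desk-scale study system: three 300-kb
#' chromosomes at 48% GC with 8-bp telomere units in 20 copies at every end,
#' one 2-kb x 20 rDNA tandem array, 322-bp LTR retrotransposons flanked by
#' TCTTG/CAACA target-site motifs (three intact, two degraded), three large
#' duplicated-segment pairs (27,850 bp with 4 mismatches + one 1-bp gap;
#' 5,100 bp; 2,500 bp) at chromosome ends, and a mating-type locus of two
#' 2-kb inverted repeats around a 19-kb invertible region. A full-scale rDNA
#' unit (8,145 bp) can be requested via `rdna_unit_length`.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param telomere_unit 5'-end telomere repeat unit; the 3' end carries its
#'   reverse complement.
#' @param telomere_copies Telomere unit copies at each end.
#' @param rdna_unit_length,rdna_copies rDNA tandem-repeat unit length and
#'   copy number (one array, on one chromosome).
#' @param ltr_length LTR length (bp) of each retrotransposon.
#' @param ltr_flank5,ltr_flank3 Target-site motifs immediately outside the
#'   5' and 3' LTRs on the element strand.
#' @param n_intact_ltr_rts,n_degraded_ltr_rts Counts of intact elements and
#'   of elements carrying ORF-breaking SNPs/indels.
#' @param ltr_orf_aa Length (aa) of the planted polyprotein ORF.
#' @param lds_specs List of duplicated-segment specs, each a list with
#'   `length`, `n_mismatch`, `n_gap` (1-bp gaps) and `terminal_motif`
#'   (one of `"none"`, `"full_unit"`, `"degenerate_unit"`).
#' @param mat_ir_length,mat_invertible_length Inverted-repeat and invertible
#'   region lengths of the mating-type locus.
#' @param polygc_tracts List of `list(base, len)` poly(GC) tracts
#'   (`base` one of `"G"`, `"C"`, `"GC"`; `len > 10`).
#' @param str_tracts List of `list(unit, copies)` short tandem repeats.
#' @param low_complexity_tracts List of `list(base, len)` homopolymers.
#' @param marked_cds_length Length of a marked single-exon CDS planted for
#'   insertion experiments (the classic 672-bp orotidine-decarboxylase CDS
#'   scale).
#' @param gc Background GC content.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_chromosomes = 3L,
                             chrom_length = 300000L,
                             telomere_unit = "ACCCCGCC",
                             telomere_copies = 20L,
                             rdna_unit_length = 2000L,
                             rdna_copies = 20L,
                             ltr_length = 322L,
                             ltr_flank5 = "TCTTG",
                             ltr_flank3 = "CAACA",
                             n_intact_ltr_rts = 3L,
                             n_degraded_ltr_rts = 2L,
                             ltr_orf_aa = 1417L,
                             lds_specs = list(
                               list(length = 27850L, n_mismatch = 4L,
                                    n_gap = 1L, terminal_motif = "none"),
                               list(length = 5100L, n_mismatch = 6L,
                                    n_gap = 2L, terminal_motif = "full_unit"),
                               list(length = 2500L, n_mismatch = 3L,
                                    n_gap = 1L,
                                    terminal_motif = "degenerate_unit")),
                             mat_ir_length = 2000L,
                             mat_invertible_length = 19000L,
                             polygc_tracts = list(
                               list(base = "G", len = 14L),
                               list(base = "C", len = 16L),
                               list(base = "GC", len = 22L),
                               list(base = "G", len = 12L)),
                             str_tracts = list(
                               list(unit = "AT", copies = 15L),
                               list(unit = "CAG", copies = 12L)),
                             low_complexity_tracts = list(
                               list(base = "A", len = 25L)),
                             marked_cds_length = 672L,
                             gc = 0.48,
                             seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              telomere_unit = telomere_unit,
              telomere_copies = as.integer(telomere_copies),
              rdna_unit_length = as.integer(rdna_unit_length),
              rdna_copies = as.integer(rdna_copies),
              ltr_length = as.integer(ltr_length),
              ltr_flank5 = ltr_flank5, ltr_flank3 = ltr_flank3,
              n_intact_ltr_rts = as.integer(n_intact_ltr_rts),
              n_degraded_ltr_rts = as.integer(n_degraded_ltr_rts),
              ltr_orf_aa = as.integer(ltr_orf_aa),
              lds_specs = lds_specs,
              mat_ir_length = as.integer(mat_ir_length),
              mat_invertible_length = as.integer(mat_invertible_length),
              polygc_tracts = polygc_tracts,
              str_tracts = str_tracts,
              low_complexity_tracts = low_complexity_tracts,
              marked_cds_length = as.integer(marked_cds_length),
              gc = gc, seed = as.integer(seed))
  lens <- c(cfg$chrom_length, cfg$telomere_copies, cfg$rdna_unit_length,
            cfg$rdna_copies, cfg$ltr_length, cfg$mat_ir_length,
            cfg$mat_invertible_length)
  if (any(lens <= 0)) stop("all lengths/counts must be positive")
  for (ls in cfg$lds_specs) {
    if (ls$length >= cfg$chrom_length / 4) {
      stop("lds length must be < chrom_length/4")
    }
    if (!ls$terminal_motif %in% c("none", "full_unit", "degenerate_unit")) {
      stop("unknown terminal_motif: ", ls$terminal_motif)
    }
  }
  for (pt in cfg$polygc_tracts) {
    if (pt$len <= 10) stop("poly(GC) tracts must be > 10 bp")
  }
  class(cfg) <- "SyntheticConfig"
  cfg
}

# random codon sequence with no in-frame stop
random_orf <- function(n_aa) {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  paste0("ATG", paste(sample(codons, n_aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

# random DNA with an exact G+C base count (used for LTRs so the GC fraction
# of detected LTRs is a fixed property of the genome, not of the draw)
random_dna_exact_gc <- function(n, n_gc) {
  v <- c(sample(c("G", "C"), n_gc, replace = TRUE),
         sample(c("A", "T"), n - n_gc, replace = TRUE))
  paste(sample(v), collapse = "")
}

# substitute preserving GC count: A<->T, G<->C
gc_preserving_subs <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  v[positions] <- chartr("ACGT", "TGCA", v[positions])
  paste(v, collapse = "")
}

# arbitrary substitutions (base -> a different base, uniformly)
substitute_bases <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  shift <- sample(1:3, length(positions), replace = TRUE)
  old <- match(v[positions], c("A", "C", "G", "T"))
  v[positions] <- c("A", "C", "G", "T")[((old - 1L + shift) %% 4L) + 1L]
  paste(v, collapse = "")
}

new_rec <- function(id, type, start, end, strand = "+", ...) {
  extra <- list(...)
  rec <- data.frame(id = id, type = type, start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    stringsAsFactors = FALSE)
  for (k in names(extra)) rec[[k]] <- extra[[k]]
  rec
}

bind_recs <- function(recs) {
  cols <- unique(unlist(lapply(recs, names)))
  out <- do.call(rbind, lapply(recs, function(r) {
    for (k in setdiff(cols, names(r))) r[[k]] <- NA
    r[cols]
  }))
  rownames(out) <- NULL
  out
}

#' Build a synthetic genome with a ground-truth manifest
#'
#' Every chromosome begins with `[telomere_unit]n` and ends with
#' `[revcomp(telomere_unit)]n`; one chromosome carries one rDNA tandem array;
#' LTR retrotransposons are planted as `flank5 + LTR + internal + LTR +
#' flank3` on their strand, with a single long ORF (degraded copies carry
#' ORF-breaking SNPs/indels); each duplicated-segment spec yields two
#' co-oriented near-identical copies at two chromosome ends, differing by
#' exactly the configured substitutions and 1-bp gaps, with any configured
#' telomere-like terminal motif at the copy 3' end; the mating-type locus is
#' IR + invertible + revcomp(IR). The manifest records exact coordinates and
#' parameters of every planted feature.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `genome` (a [genome()]) and `manifest`
#'   (list with `features` data.frame and the `config`).
#' @export
build_genome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  with_op_seed(cfg$seed, "build_genome", {
    nch <- cfg$n_chromosomes
    if (2L * length(cfg$lds_specs) > 2L * nch) {
      stop("config infeasible: more LDS copies than chromosome ends")
    }
    tel5 <- strrep(cfg$telomere_unit, cfg$telomere_copies)
    tel3 <- strrep(revcomp(cfg$telomere_unit), cfg$telomere_copies)
    unit_len <- nchar(cfg$telomere_unit)

    # ---- shared sequences -------------------------------------------------
    rdna_unit <- random_dna(cfg$rdna_unit_length, cfg$gc)
    rdna_chr <- min(2L, nch)
    mat_chr <- nch
    mat_ir <- random_dna(cfg$mat_ir_length, cfg$gc)
    mat_inv <- random_dna(cfg$mat_invertible_length, cfg$gc)

    n_ltr <- cfg$n_intact_ltr_rts + cfg$n_degraded_ltr_rts
    base_ltr <- random_dna_exact_gc(cfg$ltr_length,
                                    round(0.292 * cfg$ltr_length))
    ltr_elements <- lapply(seq_len(n_ltr), function(i) {
      ltr <- base_ltr
      if (i > 1) {
        # copy-specific GC-preserving substitutions so within-element LTR
        # pairs outscore cross-element pairings
        pos <- sample(seq_len(cfg$ltr_length), 2L * (i - 1L))
        ltr <- gc_preserving_subs(ltr, pos)
      }
      orf <- random_orf(cfg$ltr_orf_aa)
      pad1 <- random_dna(40L, cfg$gc)
      pad2 <- random_dna(40L, cfg$gc)
      # the internal region must not chance-extend the paired-LTR match
      # beyond the true LTR boundaries: its first base must differ from the
      # first base of flank3 and its last base from the last base of flank5
      nb1 <- setdiff(c("A", "C", "G", "T"),
                     substr(cfg$ltr_flank3, 1L, 1L))[1]
      nb2 <- setdiff(c("A", "C", "G", "T"),
                     substr(cfg$ltr_flank5, nchar(cfg$ltr_flank5),
                            nchar(cfg$ltr_flank5)))[1]
      pad1 <- paste0(nb1, substr(pad1, 2L, nchar(pad1)))
      pad2 <- paste0(substr(pad2, 1L, nchar(pad2) - 1L), nb2)
      degraded <- i > cfg$n_intact_ltr_rts
      n_sub_break <- 0L
      if (degraded) {
        # ORF-breaking edits: a nonsense SNP near the ORF midpoint plus an
        # upstream 1-bp deletion, placed so that no residual open frame can
        # reach a polyprotein-scale length
        codon_i <- sample(seq(floor(0.45 * cfg$ltr_orf_aa),
                              ceiling(0.55 * cfg$ltr_orf_aa)), 1L)
        orf <- splice_chr(orf, 3L * codon_i, 3L * codon_i + 3L, "TAA")
        del_codon <- sample(seq(floor(0.10 * cfg$ltr_orf_aa),
                                floor(0.30 * cfg$ltr_orf_aa)), 1L)
        del_at <- 3L * del_codon + 1L
        orf <- splice_chr(orf, del_at, del_at + 1L, "")
        n_sub_break <- 1L
      }
      internal <- paste0(pad1, orf, pad2)
      strand <- if (i %% 2L == 1L) "+" else "-"
      list(i = i, ltr = ltr, internal = internal, strand = strand,
           degraded = degraded, orf_aa = if (degraded) NA_integer_
                                          else cfg$ltr_orf_aa)
    })

    motif_seq <- function(kind) {
      switch(kind,
             none = "",
             full_unit = strrep(cfg$telomere_unit, 4L),
             degenerate_unit = strrep("ACCCGCC", 3L))
    }
    lds_pairs <- lapply(seq_along(cfg$lds_specs), function(i) {
      ls <- cfg$lds_specs[[i]]
      mot <- motif_seq(ls$terminal_motif)
      len <- ls$length
      body <- if (nchar(mot) > 0) {
        # the base before the terminal motif must not extend the motif run
        # leftwards, so detected motif copy counts are exact
        brk <- setdiff(c("A", "C", "G", "T"),
                       substr(mot, nchar(mot), nchar(mot)))[1]
        paste0(random_dna(len - nchar(mot) - 1L, cfg$gc), brk, mot)
      } else paste0(random_dna(len, cfg$gc))
      # divergence sites live in the outer fifths of the segment, away from
      # boundaries, the terminal motif, and the central collapse window;
      # they alternate between the two outer zones so both flanks of the
      # segment carry copy-specific sequence
      zoneL <- seq(200L, max(300L, floor(len / 5)))
      zoneR <- seq(min(len - 300L, ceiling(4 * len / 5)),
                   len - nchar(mot) - 200L)
      zoneR <- zoneR[zoneR > 200 & zoneR < len - nchar(mot) - 100]
      ns <- ls$n_mismatch + ls$n_gap
      nl <- ceiling(ns / 2)
      sites <- sort(c(sample(unique(zoneL), nl),
                      sample(unique(zoneR), ns - nl)))
      mm_sites <- sample(sites, ls$n_mismatch)
      gap_sites <- setdiff(sites, mm_sites)
      copyB <- substitute_bases(body, mm_sites)
      for (gpos in sort(gap_sites, decreasing = TRUE)) {
        copyB <- splice_chr(copyB, gpos, gpos + 1L, "")
      }
      list(i = i, spec = ls, copyA = body, copyB = copyB,
           motif = ls$terminal_motif,
           motif_copies = switch(ls$terminal_motif, none = 0,
                                 full_unit = 4, degenerate_unit = 3))
    })
    # assign LDS copies to chromosome ends: copy A at the 5' end of
    # chromosome i, copy B at the 3' end of chromosome (i mod n)+1
    lds_at <- list()
    for (p in lds_pairs) {
      a_chr <- ((p$i - 1L) %% nch) + 1L
      b_chr <- (p$i %% nch) + 1L
      lds_at[[paste0(a_chr, "_5")]] <- list(pair = p, copy = "A")
      lds_at[[paste0(b_chr, "_3")]] <- list(pair = p, copy = "B")
    }

    cds_seq <- random_orf(cfg$marked_cds_length %/% 3L - 1L)

    # ---- interior feature queues per chromosome ---------------------------
    interior <- vector("list", nch)
    add_interior <- function(chr, item) {
      interior[[chr]][[length(interior[[chr]]) + 1L]] <<- item
    }
    add_interior(rdna_chr, list(type = "rdna",
                                seq = strrep(rdna_unit, cfg$rdna_copies)))
    add_interior(mat_chr, list(type = "mat",
                               seq = paste0(mat_ir, mat_inv, revcomp(mat_ir))))
    add_interior(1L, list(type = "marked_cds", seq = cds_seq))
    for (el in ltr_elements) {
      blk <- paste0(cfg$ltr_flank5, el$ltr, el$internal, el$ltr,
                    cfg$ltr_flank3)
      if (el$strand == "-") blk <- revcomp(blk)
      add_interior(((el$i - 1L) %% nch) + 1L,
                   list(type = "ltr", seq = blk, el = el))
    }
    ti <- 0L
    for (pt in cfg$polygc_tracts) {
      ti <- ti + 1L
      s <- if (pt$base == "GC") {
        paste(sample(c("G", "C"), pt$len, replace = TRUE), collapse = "")
      } else strrep(pt$base, pt$len)
      add_interior(((ti - 1L) %% nch) + 1L,
                   list(type = "polygc", pre = "AT", core = s, post = "TA"))
    }
    for (st in cfg$str_tracts) {
      ti <- ti + 1L
      add_interior(((ti - 1L) %% nch) + 1L,
                   list(type = "str", pre = "G",
                        core = strrep(st$unit, st$copies), post = "C",
                        unit = st$unit))
    }
    for (lc in cfg$low_complexity_tracts) {
      ti <- ti + 1L
      add_interior(((ti - 1L) %% nch) + 1L,
                   list(type = "low_complexity", pre = "G",
                        core = strrep(lc$base, lc$len), post = "C"))
    }

    # ---- assemble chromosomes --------------------------------------------
    # each feature part carries pre/core/post sequence; only the core is
    # recorded in the manifest. The single pre/post pad bases deterministically
    # break tandem-array periodicity at planted boundaries so detectors can
    # recover exact coordinates.
    not_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
    unit3 <- revcomp(cfg$telomere_unit)
    contigs <- character(nch)
    names(contigs) <- paste0("chr", seq_len(nch))
    recs <- list()
    for (chr in seq_len(nch)) {
      cname <- paste0("chr", chr)
      mkpart <- function(type, core, pre = "", post = "", extra = NULL) {
        c(list(type = type, pre = pre, core = core, post = post), extra)
      }
      parts <- list(mkpart("tel5", tel5,
                           post = not_base(substr(cfg$telomere_unit, 1, 1))))
      lds_part <- function(slot) {
        p <- lds_at[[slot]]
        mkpart("lds", if (p$copy == "A") p$pair$copyA else p$pair$copyB,
               extra = list(pair = p$pair, copy = p$copy))
      }
      k5 <- paste0(chr, "_5")
      if (!is.null(lds_at[[k5]])) {
        # short spacer keeps the duplicated segment inside the
        # subtelomeric window, abutting the telomere
        parts <- c(parts, list(mkpart("sspacer", "")), list(lds_part(k5)))
      }
      for (item in interior[[chr]]) {
        fp <- if (item$type == "rdna") {
          mkpart("rdna", item$seq,
                 pre = not_base(substr(rdna_unit, cfg$rdna_unit_length,
                                       cfg$rdna_unit_length)),
                 post = not_base(substr(rdna_unit, 1, 1)))
        } else if (!is.null(item$core)) {
          mkpart(item$type, item$core, pre = item$pre, post = item$post,
                 extra = item[setdiff(names(item),
                                      c("type", "pre", "core", "post"))])
        } else {
          mkpart(item$type, item$seq,
                 extra = item[setdiff(names(item), c("type", "seq"))])
        }
        parts <- c(parts, list(mkpart("spacer", "")), list(fp))
      }
      k3 <- paste0(chr, "_3")
      if (!is.null(lds_at[[k3]])) {
        parts <- c(parts, list(mkpart("spacer", "")), list(lds_part(k3)))
      }
      parts <- c(parts, list(mkpart("sspacer", "")),
                 list(mkpart("tel3", tel3,
                             pre = not_base(substr(unit3, unit_len,
                                                   unit_len)))))
      fixed <- sum(vapply(parts, function(p) {
        if (p$type %in% c("spacer", "sspacer")) 0L
        else nchar(p$pre) + nchar(p$core) + nchar(p$post)
      }, integer(1)))
      n_sp <- sum(vapply(parts, function(p) p$type == "spacer", logical(1)))
      n_ssp <- sum(vapply(parts, function(p) p$type == "sspacer",
                          logical(1)))
      ssp_len <- sample(300:800, n_ssp, replace = TRUE)
      rem <- cfg$chrom_length - fixed - sum(ssp_len)
      if (rem < 400L * n_sp) {
        stop("config infeasible for chrom_length: chr", chr,
             " needs ", fixed + sum(ssp_len) + 400L * n_sp, " bp")
      }
      w <- runif(n_sp, 0.5, 1.5)
      sp_len <- pmax(400L, as.integer(floor(rem * w / sum(w))))
      sp_len[n_sp] <- rem - sum(sp_len[-n_sp])
      si <- 0L
      ssi <- 0L
      pos <- 0L
      pieces <- character(length(parts))
      for (pi in seq_along(parts)) {
        p <- parts[[pi]]
        if (p$type %in% c("spacer", "sspacer")) {
          if (p$type == "spacer") {
            si <- si + 1L
            len_sp <- sp_len[si]
          } else {
            ssi <- ssi + 1L
            len_sp <- ssp_len[ssi]
          }
          s <- random_dna(len_sp, cfg$gc)
        } else {
          s <- paste0(p$pre, p$core, p$post)
          st <- pos + nchar(p$pre)
          en <- st + nchar(p$core)
          recs[[length(recs) + 1L]] <- switch(
            p$type,
            tel5 = new_rec(paste0("tel_", cname, "_5"), "telomere", st, en,
                           contig = cname, side = "5prime",
                           unit = cfg$telomere_unit,
                           copies = cfg$telomere_copies),
            tel3 = new_rec(paste0("tel_", cname, "_3"), "telomere", st, en,
                           contig = cname, side = "3prime",
                           unit = revcomp(cfg$telomere_unit),
                           copies = cfg$telomere_copies),
            rdna = new_rec("rdna", "rdna_array", st, en, contig = cname,
                           unit_length = cfg$rdna_unit_length,
                           copies = cfg$rdna_copies, unit = rdna_unit),
            mat = {
              irl <- cfg$mat_ir_length
              invl <- cfg$mat_invertible_length
              new_rec("mat", "mat_locus", st, en, contig = cname,
                      ir_length = irl, invertible_length = invl,
                      ir1_start = st, ir1_end = st + irl,
                      inv_start = st + irl, inv_end = st + irl + invl,
                      ir2_start = st + irl + invl, ir2_end = en)
            },
            marked_cds = new_rec("marked_cds", "marked_cds", st, en,
                                 contig = cname,
                                 cds_length = cfg$marked_cds_length),
            ltr = {
              el <- p$el
              flen <- nchar(cfg$ltr_flank5)
              ll <- cfg$ltr_length
              ilen <- nchar(el$internal)
              # element proper excludes the target-site flanks
              es <- st + flen
              ee <- en - nchar(cfg$ltr_flank3)
              new_rec(paste0("ltr_rt", el$i), "ltr_rt", es, ee,
                      strand = el$strand, contig = cname,
                      ltr_length = ll, internal_length = ilen,
                      intact = !el$degraded, orf_aa = el$orf_aa,
                      ltr5_start = es, ltr5_end = es + ll,
                      ltr3_start = ee - ll, ltr3_end = ee)
            },
            lds = {
              pr <- p$pair
              new_rec(paste0("LDS", pr$i, "_", p$copy), "lds_copy", st, en,
                      contig = cname, pair_id = paste0("LDS", pr$i),
                      copy = p$copy, n_mismatch = pr$spec$n_mismatch,
                      n_gap = pr$spec$n_gap,
                      terminal_motif = pr$motif,
                      motif_copies = pr$motif_copies)
            },
            polygc = new_rec(paste0("polygc", st), "polygc", st, en,
                             contig = cname, len = en - st),
            str = new_rec(paste0("str", st), "str", st, en, contig = cname,
                          unit = p$unit),
            low_complexity = new_rec(paste0("lc", st), "low_complexity",
                                     st, en, contig = cname))
        }
        pieces[pi] <- s
        pos <- pos + nchar(s)
      }
      contigs[[cname]] <- paste(pieces, collapse = "")
      stopifnot(nchar(contigs[[cname]]) == cfg$chrom_length)
    }
    feats <- bind_recs(recs)
    # reorder columns: id/type/contig/interval first
    lead <- c("id", "type", "contig", "start", "end", "strand")
    feats <- feats[, c(lead, setdiff(names(feats), lead))]
    g <- genome(contigs, label = "synthetic_truth")
    list(genome = g, manifest = list(features = feats, config = cfg))
  })
}

#' Insert a sequence into a genome at a given position
#'
#' Utility for planting small variants (e.g. a 5-bp insertion into a marked
#' CDS to emulate a frame-shift knockout).
#'
#' @param g A `Genome`.
#' @param contig Contig name.
#' @param pos 0-based position; `seq` is inserted so that it starts at `pos`.
#' @param seq Sequence to insert.
#' @return Modified `Genome`.
#' @export
apply_insertion <- function(g, contig, pos, seq) {
  s <- contig_seq(g, contig)
  stopifnot(pos >= 0, pos <= nchar(s))
  g$contigs[[contig]] <- splice_chr(s, pos, pos, seq)
  g
}

#' Mutate a genome with random substitutions
#'
#' @param g A `Genome`.
#' @param sub_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Mutated `Genome`.
#' @export
mutate_genome <- function(g, sub_rate = 0.005, seed = 1L) {
  with_op_seed(seed, "mutate_genome", {
    for (nm in names(g$contigs)) {
      s <- g$contigs[[nm]]
      n <- nchar(s)
      k <- rbinom(1L, n, sub_rate)
      if (k > 0) {
        s <- substitute_bases(s, sample.int(n, k))
        g$contigs[[nm]] <- s
      }
    }
    g$label <- paste0(g$label, "_mut")
    g
  })
}

#' Derive a defective alternate assembly from a synthetic truth genome
#'
#' Applies assembly-defect and true-variant edits to a copy of the genome,
#' emulating a second, independently assembled strain: collapsed duplicated
#' segments, dropped LTR retrotransposons, truncated rDNA arrays,
#' over-assembled chromosome ends, a mating-type inversion, and genuine
#' insertions/deletions. Each edit is truth-labelled `assembly_error`,
#' `mat_switch` or `true_sv`.
#'
#' @param g Truth `Genome` from [build_genome()].
#' @param manifest Matching manifest.
#' @param defects List of defect specs; each element is a list with one of:
#'   `collapse_lds` (pair id, with optional `drop_bp`, default 14090, and
#'   `copy`, default `"A"`), `drop_ltr_rt` (element id), `truncate_rdna_to`
#'   (copy count), `overassemble_end` (list `contig`, `extra`),
#'   `invert_mat = TRUE`, or `true_sv` (list `mode` = `"delete"` or
#'   `"insert"`, `length`).
#' @param seed Integer seed for random defect sequence content.
#' @return List with `genome` (the alternate assembly) and `truth`
#'   (data.frame of defect records with labels and truth coordinates in the
#'   original genome).
#' @export
derive_alternate_assembly <- function(g, manifest, defects, seed = 1L) {
  feats <- manifest$features
  get_feat <- function(id) {
    r <- feats[feats$id == id, , drop = FALSE]
    if (nrow(r) == 0) stop("unknown defect target: ", id)
    r
  }
  with_op_seed(seed, "derive_alternate_assembly", {
    edits <- list()   # each: contig, start, end, replacement, label, size, kind
    truth <- list()
    add_edit <- function(contig, start, end, repl, label, kind, id) {
      edits[[length(edits) + 1L]] <<- list(contig = contig, start = start,
                                           end = end, repl = repl)
      truth[[length(truth) + 1L]] <<- data.frame(
        defect = id, label = label, kind = kind, contig = contig,
        start = as.integer(start), end = as.integer(end),
        size = as.integer(abs((end - start) - nchar(repl))),
        stringsAsFactors = FALSE)
    }
    safe_spot <- function(len) {
      # a position not within `len`+margin of any planted feature or of a
      # previously placed defect
      for (try in 1:200) {
        chr <- sample(names(g$contigs), 1L)
        cl <- nchar(g$contigs[[chr]])
        pos <- sample.int(cl - len - 4000L, 1L) + 2000L
        f <- feats[feats$contig == chr, , drop = FALSE]
        clash <- any(overlaps(pos - 500L, pos + len + 500L, f$start, f$end))
        for (e in edits) {
          if (e$contig == chr &&
              overlaps(pos - 2000L, pos + len + 2000L, e$start,
                       max(e$end, e$start + nchar(e$repl)))) {
            clash <- TRUE
          }
        }
        if (!clash) return(list(contig = chr, pos = pos))
      }
      stop("no feature-free interval of ", len, " bp found")
    }
    for (d in defects) {
      if (!is.null(d$collapse_lds)) {
        copy <- if (is.null(d$copy)) "A" else d$copy
        drop_bp <- if (is.null(d$drop_bp)) 14090L else as.integer(d$drop_bp)
        r <- get_feat(paste0(d$collapse_lds, "_", copy))
        len <- r$end - r$start
        if (drop_bp >= len) stop("drop_bp exceeds segment length")
        s0 <- r$start + (len - drop_bp) %/% 2L
        add_edit(r$contig, s0, s0 + drop_bp, "", "assembly_error",
                 "collapsed_lds", r$id)
      } else if (!is.null(d$drop_ltr_rt)) {
        r <- get_feat(d$drop_ltr_rt)
        add_edit(r$contig, r$start, r$end, "", "assembly_error",
                 "dropped_ltr_rt", r$id)
      } else if (!is.null(d$truncate_rdna_to)) {
        r <- get_feat("rdna")
        keep <- as.integer(d$truncate_rdna_to)
        if (keep >= r$copies) stop("truncate_rdna_to >= planted copies")
        cut <- (r$copies - keep) * r$unit_length
        add_edit(r$contig, r$start, r$start + cut, "", "assembly_error",
                 "truncated_rdna", "rdna")
      } else if (!is.null(d$overassemble_end)) {
        chr <- d$overassemble_end$contig
        extra <- as.integer(d$overassemble_end$extra)
        cl <- nchar(g$contigs[[chr]])
        add_edit(chr, cl, cl, random_dna(extra, 0.48), "assembly_error",
                 "overassembled_end", paste0("over_", chr))
      } else if (isTRUE(d$invert_mat)) {
        r <- get_feat("mat")
        add_edit(r$contig, r$inv_start, r$inv_end,
                 revcomp(subseq_chr(g$contigs[[r$contig]], r$inv_start,
                                    r$inv_end)),
                 "mat_switch", "mat_inversion", "mat")
      } else if (!is.null(d$true_sv)) {
        sv <- d$true_sv
        len <- as.integer(sv$length)
        spot <- safe_spot(len)
        if (identical(sv$mode, "insert")) {
          add_edit(spot$contig, spot$pos, spot$pos, random_dna(len, 0.48),
                   "true_sv", "insertion_in_b", paste0("ins_", spot$pos))
        } else {
          add_edit(spot$contig, spot$pos, spot$pos + len, "", "true_sv",
                   "deletion_in_b", paste0("del_", spot$pos))
        }
      } else {
        stop("unrecognised defect spec")
      }
    }
    # apply per contig from high to low coordinates
    b <- g
    ord <- order(vapply(edits, function(e) e$contig, character(1)),
                 -vapply(edits, function(e) e$start, numeric(1)))
    for (e in edits[ord]) {
      b$contigs[[e$contig]] <- splice_chr(b$contigs[[e$contig]], e$start,
                                          e$end, e$repl)
    }
    b$label <- "synthetic_alternate"
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(genome = b, truth = truth)
  })
}

# vectorised error process over a character vector of bases; returns string
apply_read_errors <- function(v, sub_rate, ins_rate, del_rate) {
  n <- length(v)
  if (del_rate > 0) {
    v <- v[runif(n) >= del_rate]
    n <- length(v)
  }
  if (n == 0) return("")
  if (sub_rate > 0) {
    i <- which(runif(n) < sub_rate)
    if (length(i)) {
      old <- match(v[i], c("A", "C", "G", "T"))
      shift <- sample(1:3, length(i), replace = TRUE)
      v[i] <- c("A", "C", "G", "T")[((old - 1L + shift) %% 4L) + 1L]
    }
  }
  if (ins_rate > 0) {
    m <- runif(n) < ins_rate
    ni <- sum(m)
    if (ni > 0) {
      out <- character(n + ni)
      ci <- cumsum(m)
      orig <- seq_len(n) + c(0L, ci[-n])
      out[orig] <- v
      out[orig[m] + 1L] <- sample(c("A", "C", "G", "T"), ni, replace = TRUE)
      v <- out
    }
  }
  paste(v, collapse = "")
}

#' Simulate long reads with indel-dominant errors
#'
#' Emulates the long-read regime used for assembly curation: reads in the
#' tens of kilobases with an error process dominated by short insertions and
#' deletions. Reads are sampled uniformly with random strand; read length is
#' capped at a third of the shortest contig so that no read spans a whole
#' chromosome.
#'
#' @param g A `Genome` to sample from.
#' @param mean_len,len_sd Read-length distribution (bp).
#' @param coverage Target mean coverage.
#' @param sub_rate,ins_rate,del_rate Per-base error rates (each in
#'   `[0, 0.2]`).
#' @param min_len Minimum read length.
#' @param seed Integer seed.
#' @return A `ReadSet` with per-read truth (origin interval, strand, error
#'   counts).
#' @export
simulate_long_reads <- function(g, mean_len = 25000, len_sd = 6000,
                                coverage = 30, sub_rate = 0.002,
                                ins_rate = 0.006, del_rate = 0.006,
                                min_len = 1000, seed = 1L) {
  stopifnot(coverage > 0)
  rates <- c(sub_rate, ins_rate, del_rate)
  stopifnot(all(rates >= 0 & rates <= 0.2))
  with_op_seed(seed, "simulate_long_reads", {
    G <- genome_length(g)
    cap <- floor(min(nchar(g$contigs)) / 3)
    nr <- ceiling(coverage * G / min(mean_len, cap))
    cl <- nchar(g$contigs)
    cn <- names(g$contigs)
    chrs <- sample(cn, nr, replace = TRUE, prob = cl / sum(cl))
    lens <- pmin(cap, pmax(min_len, round(rnorm(nr, mean_len, len_sd))))
    lens <- pmin(lens, cl[chrs])
    starts <- floor(runif(nr) * (cl[chrs] - lens + 1))
    strands <- sample(c("+", "-"), nr, replace = TRUE)
    seqs <- character(nr)
    nsub <- nins <- ndel <- integer(nr)
    for (i in seq_len(nr)) {
      s <- subseq_chr(g$contigs[[chrs[i]]], starts[i], starts[i] + lens[i])
      v <- strsplit(s, "")[[1]]
      out <- apply_read_errors(v, sub_rate, ins_rate, del_rate)
      seqs[i] <- out
    }
    if (any(strands == "-")) {
      neg <- which(strands == "-")
      seqs[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[neg])))
    }
    nms <- sprintf("lr%06d", seq_len(nr))
    names(seqs) <- nms
    truth <- data.frame(name = nms, contig = chrs, start = as.integer(starts),
                        end = as.integer(starts + lens), strand = strands,
                        stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    read_set(seqs, truth)
  })
}

#' Simulate short reads with systematic poly(GC) errors
#'
#' Emulates short-read data whose only weakness is long G/C tracts: outside
#' poly(GC) runs reads carry independent substitution noise; inside maximal
#' G/C runs of at least `run_min` bases, every read fully covering the run
#' is corrupted with probability `error_prob` towards a per-locus fixed
#' wrong allele (one base shrunk, extended, or substituted), so that naive
#' majority polishing is corrupted there while remaining correct elsewhere.
#'
#' @param g A `Genome` to sample from.
#' @param read_len Read length (bp).
#' @param coverage Target mean coverage.
#' @param sub_rate Background substitution rate.
#' @param polygc_error List with `run_min` (default 11), `error_prob`
#'   (default 0.3) and `mode` (`"shrink"`, `"extend"` or `"substitute"`).
#' @param paired If `TRUE`, reads are emitted as fragment mate pairs.
#' @param insert_size Fragment length for paired mode.
#' @param seed Integer seed.
#' @return A `ReadSet` with per-read truth.
#' @export
simulate_short_reads <- function(g, read_len = 150, coverage = 60,
                                 sub_rate = 0.001,
                                 polygc_error = list(run_min = 11,
                                                     error_prob = 0.3,
                                                     mode = "shrink"),
                                 paired = FALSE, insert_size = 400,
                                 seed = 1L) {
  stopifnot(coverage > 0, sub_rate >= 0, sub_rate <= 0.2)
  if (read_len > min(nchar(g$contigs))) {
    stop("read_len exceeds the shortest contig")
  }
  with_op_seed(seed, "simulate_short_reads", {
    runs <- detect_polygc(g, run_min = polygc_error$run_min)
    G <- genome_length(g)
    cl <- nchar(g$contigs)
    cn <- names(g$contigs)
    if (paired) {
      stopifnot(insert_size >= read_len,
                insert_size <= min(cl))
      nfrag <- ceiling(coverage * G / (2 * read_len))
      fchrs <- sample(cn, nfrag, replace = TRUE, prob = cl / sum(cl))
      fstarts <- floor(runif(nfrag) * (cl[fchrs] - insert_size + 1))
      nr <- 2L * nfrag
      chrs <- rep(fchrs, each = 2L)
      starts <- as.vector(rbind(fstarts,
                                fstarts + insert_size - read_len))
      strands <- rep(c("+", "-"), nfrag)
    } else {
      nr <- ceiling(coverage * G / read_len)
      chrs <- sample(cn, nr, replace = TRUE, prob = cl / sum(cl))
      starts <- floor(runif(nr) * (cl[chrs] - read_len + 1))
      strands <- sample(c("+", "-"), nr, replace = TRUE)
    }
    seqs <- substring(g$contigs[chrs], starts + 1L, starts + read_len)
    ends <- starts + read_len
    # per-locus fixed wrong allele for each poly(GC) run
    sys_edit <- NULL
    if (nrow(runs) > 0) {
      mode <- polygc_error$mode
      runs$allele_pos <- runs$start + (runs$end - runs$start) %/% 2L
      runs$wrong_base <- vapply(seq_len(nrow(runs)), function(i) {
        cur <- substr(g$contigs[[runs$contig[i]]], runs$allele_pos[i] + 1L,
                      runs$allele_pos[i] + 1L)
        if (cur == "G") "C" else "G"
      }, character(1))
    }
    err_reads <- integer(0)
    if (nrow(runs) > 0 && polygc_error$error_prob > 0) {
      for (i in seq_len(nrow(runs))) {
        cover <- which(chrs == runs$contig[i] & starts <= runs$start[i] &
                         ends >= runs$end[i])
        hit <- cover[runif(length(cover)) < polygc_error$error_prob]
        for (ri in hit) {
          off <- runs$start[i] - starts[ri]  # 0-based offset of run in read
          s <- seqs[ri]
          if (polygc_error$mode == "shrink") {
            s <- splice_chr(s, off, off + 1L, "")
          } else if (polygc_error$mode == "extend") {
            s <- splice_chr(s, off, off,
                            substr(s, off + 1L, off + 1L))
          } else {
            mid <- runs$allele_pos[i] - starts[ri]
            s <- splice_chr(s, mid, mid + 1L, runs$wrong_base[i])
          }
          seqs[ri] <- s
        }
        err_reads <- c(err_reads, hit)
      }
    }
    # background iid substitutions, masked out of poly(GC) runs
    nerr <- rbinom(1L, nr * read_len, sub_rate)
    if (nerr > 0) {
      ridx <- sample.int(nr, nerr, replace = TRUE)
      # only clean (unshifted) coordinates are safe targets
      ridx <- ridx[!(ridx %in% err_reads)]
      off <- sample.int(read_len, length(ridx), replace = TRUE) - 1L
      gpos <- starts[ridx] + off
      bad <- rep(FALSE, length(ridx))
      if (nrow(runs) > 0) {
        for (i in seq_len(nrow(runs))) {
          bad <- bad | (chrs[ridx] == runs$contig[i] &
                          gpos >= runs$start[i] & gpos < runs$end[i])
        }
      }
      ridx <- ridx[!bad]; off <- off[!bad]
      for (j in seq_along(ridx)) {
        ri <- ridx[j]
        cur <- substr(seqs[ri], off[j] + 1L, off[j] + 1L)
        new <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        seqs[ri] <- splice_chr(seqs[ri], off[j], off[j] + 1L, new)
      }
    }
    if (any(strands == "-")) {
      neg <- which(strands == "-")
      seqs[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[neg])))
    }
    nms <- if (paired) {
      sprintf("sr%07d/%d", rep(seq_len(nr %/% 2L), each = 2L),
              rep(1:2, nr %/% 2L))
    } else sprintf("sr%07d", seq_len(nr))
    names(seqs) <- nms
    truth <- data.frame(name = nms, contig = chrs, start = as.integer(starts),
                        end = as.integer(ends), strand = strands,
                        stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    read_set(seqs, truth)
  })
}
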
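# Anchor-based synteny between two assemblies, structural-variant calling
# and evidence-based classification (true variant / collapsed-repeat
# misassembly / inverted-repeat-mediated mating-type switch), and
# mating-type switch frequency estimation from long reads.

# collect anchor chains between two genomes (both orientations); returns a
# data.frame of chains in genome coordinates
synteny_chains <- function(a, b, k = 21L, max_occ = 4L,
                           max_diag_gap = 32L, min_anchors = 20L) {
  out <- list()
  for (ca in names(a$contigs)) {
    sa <- a$contigs[[ca]]
    for (cb in names(b$contigs)) {
      sb <- b$contigs[[cb]]
      for (orient in c("same", "inverted")) {
        sb2 <- if (orient == "same") sb else revcomp(sb)
        anc <- cpp_kmer_matches(sa, sb2, as.integer(k), as.integer(max_occ))
        chains <- chain_anchors(anc$apos, anc$bpos, k,
                                max_diag_gap = max_diag_gap,
                                min_anchors = min_anchors,
                                max_pos_gap = 5000L)
        for (ch in chains) {
          bs <- ch$b_start; be <- ch$b_end
          if (orient == "inverted") {
            tmp <- nchar(sb) - be
            be <- nchar(sb) - bs
            bs <- tmp
          }
          out[[length(out) + 1L]] <- data.frame(
            contig_a = ca, start_a = ch$a_start, end_a = ch$a_end,
            contig_b = cb, start_b = bs, end_b = be,
            orientation = orient, n_anchors = ch$n,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig_a = character(0), start_a = integer(0),
                      end_a = integer(0), contig_b = character(0),
                      start_b = integer(0), end_b = integer(0),
                      orientation = character(0), n_anchors = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# greedy conflict filter: accept chains by anchor count provided they do not
# substantially overlap an accepted chain on either genome
filter_chains <- function(ch, max_overlap = 0.2) {
  if (nrow(ch) == 0) return(ch)
  ch <- ch[order(-ch$n_anchors), , drop = FALSE]
  keep <- rep(TRUE, nrow(ch))
  for (i in seq_len(nrow(ch))) {
    if (!keep[i]) next
    if (i >= nrow(ch)) next
    for (j in seq(i + 1L, nrow(ch))) {
      if (!keep[j]) next
      ov_a <- if (ch$contig_a[i] == ch$contig_a[j]) {
        max(0, min(ch$end_a[i], ch$end_a[j]) -
              max(ch$start_a[i], ch$start_a[j]))
      } else 0
      ov_b <- if (ch$contig_b[i] == ch$contig_b[j]) {
        max(0, min(ch$end_b[i], ch$end_b[j]) -
              max(ch$start_b[i], ch$start_b[j]))
      } else 0
      la <- ch$end_a[j] - ch$start_a[j]
      lb <- ch$end_b[j] - ch$start_b[j]
      if (ov_a > max_overlap * la || ov_b > max_overlap * lb) {
        keep[j] <- FALSE
      }
    }
  }
  ch[keep, , drop = FALSE]
}

#' Anchor-based synteny between two assemblies
#'
#' Shared k-mers (at most `max_occ` occurrences per genome) are chained by
#' diagonal into collinear blocks, same or inverted orientation; chained
#' spans are aligned with a banded global aligner for identity.
#' Whole-genome identity is the length-weighted mean identity over syntenic
#' regions; per-genome coverage fractions are reported.
#'
#' @param a,b `Genome` objects.
#' @param k Anchor k-mer length.
#' @param align Compute per-region identity by banded alignment (set to
#'   `FALSE` to skip when only the region structure is needed, e.g. for
#'   variant calling).
#' @return list of class `Synteny`: `regions` data.frame (intervals in both
#'   genomes, `orientation`, `identity`, `columns`), `weighted_identity`,
#'   `coverage_a`, `coverage_b`.
#' @export
anchor_synteny <- function(a, b, k = 21L, align = TRUE) {
  stopifnot(inherits(a, "Genome"), inherits(b, "Genome"))
  raw <- synteny_chains(a, b, k = k)
  # syntenic regions are built from co-oriented chains only; inverted
  # chains are kept aside as evidence for inversion calling (an inverted
  # span between two co-oriented chains is an SV, not a syntenic region)
  ch <- filter_chains(raw[raw$orientation == "same", , drop = FALSE])
  inv_raw <- raw[raw$orientation == "inverted", , drop = FALSE]
  if (nrow(ch) == 0) {
    warning("no shared unique k-mers between assemblies")
    return(structure(list(regions = ch, inv_chains = inv_raw,
                          weighted_identity = NA_real_,
                          coverage_a = 0, coverage_b = 0),
                     class = "Synteny"))
  }
  # re-bridge anchor-free but identical gaps (e.g. the interior of a large
  # tandem array, where k-mers are too repetitive to anchor): consecutive
  # co-oriented chains with no diagonal jump whose gap contents align at
  # high identity are merged back into one region
  ch <- ch[order(ch$contig_a, ch$contig_b, ch$orientation, ch$start_a), ,
           drop = FALSE]
  merged <- list()
  i <- 1L
  while (i <= nrow(ch)) {
    cur <- ch[i, ]
    j <- i + 1L
    while (j <= nrow(ch) &&
           ch$contig_a[j] == cur$contig_a &&
           ch$contig_b[j] == cur$contig_b &&
           ch$orientation[j] == "same" && cur$orientation == "same" &&
           ch$start_a[j] >= cur$end_a && ch$start_b[j] >= cur$end_b) {
      gap_a <- ch$start_a[j] - cur$end_a
      gap_b <- ch$start_b[j] - cur$end_b
      if (abs(gap_a - gap_b) >= 32L || max(gap_a, gap_b) > 300000L) break
      bridge <- TRUE
      if (max(gap_a, gap_b) > 0) {
        ga <- subseq_chr(a$contigs[[cur$contig_a]], cur$end_a,
                         ch$start_a[j])
        gb <- subseq_chr(b$contigs[[cur$contig_b]], cur$end_b,
                         ch$start_b[j])
        if (identical(ga, gb)) {
          bridge <- TRUE
        } else {
          al <- cpp_banded_align(ga, gb, abs(gap_a - gap_b) + 64L)
          bridge <- al$columns > 0 &&
            (1 - (al$n_mismatch + al$n_gap_columns) / al$columns) >= 0.95
        }
      }
      if (!bridge) break
      cur$end_a <- ch$end_a[j]
      cur$end_b <- ch$end_b[j]
      cur$n_anchors <- cur$n_anchors + ch$n_anchors[j]
      j <- j + 1L
    }
    merged[[length(merged) + 1L]] <- cur
    i <- j
  }
  ch <- do.call(rbind, merged)
  ident <- rep(NA_real_, nrow(ch))
  cols <- as.integer(ch$end_a - ch$start_a)
  if (align) {
    for (i in seq_len(nrow(ch))) {
      sa <- subseq_chr(a$contigs[[ch$contig_a[i]]], ch$start_a[i],
                       ch$end_a[i])
      sb <- subseq_chr(b$contigs[[ch$contig_b[i]]], ch$start_b[i],
                       ch$end_b[i])
      if (ch$orientation[i] == "inverted") sb <- revcomp(sb)
      if (identical(sa, sb)) {
        ident[i] <- 1; cols[i] <- nchar(sa)
      } else {
        al <- cpp_banded_align(sa, sb, abs(nchar(sa) - nchar(sb)) + 64L)
        ident[i] <- 1 - (al$n_mismatch + al$n_gap_columns) / al$columns
        cols[i] <- al$columns
      }
    }
  }
  ch$identity <- ident
  ch$columns <- cols
  ch <- ch[order(ch$contig_a, ch$start_a), , drop = FALSE]
  rownames(ch) <- NULL
  structure(list(
    regions = ch,
    inv_chains = inv_raw,
    weighted_identity = sum(ident * cols) / sum(cols),
    coverage_a = sum(ch$end_a - ch$start_a) / genome_length(a),
    coverage_b = sum(ch$end_b - ch$start_b) / genome_length(b)),
    class = "Synteny")
}

#' @export
print.Synteny <- function(x, ...) {
  cat(sprintf(
    "Synteny: %d regions; weighted identity %.4f; coverage a=%.1f%% b=%.1f%%\n",
    nrow(x$regions), x$weighted_identity, 100 * x$coverage_a,
    100 * x$coverage_b))
  invisible(x)
}

empty_sv_df <- function() {
  data.frame(sv_type = character(0), contig_a = character(0),
             start_a = integer(0), end_a = integer(0),
             contig_b = character(0), start_b = integer(0),
             end_b = integer(0), size = integer(0),
             classification = character(0), n_spanning = integer(0),
             overlaps_repeat = logical(0), repeat_kind = character(0),
             ir_flanked = logical(0), stringsAsFactors = FALSE)
}

sv_row <- function(sv_type, ca, sa, ea, cb, sb, eb, size) {
  data.frame(sv_type = sv_type, contig_a = ca, start_a = as.integer(sa),
             end_a = as.integer(ea), contig_b = cb, start_b = as.integer(sb),
             end_b = as.integer(eb), size = as.integer(size),
             classification = "unclassified", n_spanning = NA_integer_,
             overlaps_repeat = NA, repeat_kind = "none", ir_flanked = NA,
             stringsAsFactors = FALSE)
}

#' Call structural variants from synteny
#'
#' Gaps and discordances between adjacent syntenic chains are typed:
#' a span present only in genome `a` is a `deletion` (missing from `b`), a
#' span present only in `b` is an `insertion_in_b`, an orientation flip
#' bounded by same-contig chains is an `inversion`, a chain pairing a
#' contig with a non-dominant partner is a `translocation`, and mutually
#' unaligned spans on both sides are a `substitution_block`. Indel sizes
#' come from the diagonal jump between chains, so they are exact even when
#' flanking repeats blur chain boundaries. Variants smaller than `min_sv`
#' are counted as small indels, not reported as SVs.
#'
#' @param synteny A `Synteny` from [anchor_synteny()].
#' @param a,b The two `Genome`s.
#' @param min_sv Minimum SV size (bp).
#' @return data.frame of variants (deterministically ordered by contig,
#'   start, type) with an `n_small_indels` attribute.
#' @export
call_svs <- function(synteny, a, b, min_sv = 50L) {
  reg <- synteny$regions
  svs <- list()
  n_small <- 0L
  if (nrow(reg) == 0) return(empty_sv_df())
  # dominant contig pairing by aligned span
  agg <- stats::aggregate(end_a - start_a ~ contig_a + contig_b,
                          data = reg, FUN = sum)
  names(agg)[3] <- "span"
  agg <- agg[order(-agg$span), ]
  dom <- agg[!duplicated(agg$contig_a), c("contig_a", "contig_b")]
  inv_all <- synteny$inv_chains
  if (is.null(inv_all)) inv_all <- reg[reg$orientation == "inverted", ,
                                       drop = FALSE]
  for (i in seq_len(nrow(dom))) {
    ca <- dom$contig_a[i]; cb <- dom$contig_b[i]
    rr <- reg[reg$contig_a == ca & reg$contig_b == cb, , drop = FALSE]
    fw <- rr[rr$orientation == "same", , drop = FALSE]
    inv <- inv_all[inv_all$contig_a == ca & inv_all$contig_b == cb, ,
                   drop = FALSE]
    fw <- fw[order(fw$start_a), , drop = FALSE]
    # translocations: chains from ca to other contigs
    tr <- reg[reg$contig_a == ca & reg$contig_b != cb, , drop = FALSE]
    for (t in seq_len(nrow(tr))) {
      if (tr$end_a[t] - tr$start_a[t] >= min_sv) {
        svs[[length(svs) + 1L]] <- sv_row(
          "translocation", ca, tr$start_a[t], tr$end_a[t], tr$contig_b[t],
          tr$start_b[t], tr$end_b[t], tr$end_a[t] - tr$start_a[t])
      }
    }
    if (nrow(fw) == 0) next
    if (nrow(fw) > 1) {
      for (j in seq_len(nrow(fw) - 1L)) {
        gap_a <- fw$start_a[j + 1L] - fw$end_a[j]
        gap_b <- fw$start_b[j + 1L] - fw$end_b[j]
        jump <- gap_a - gap_b   # diagonal jump: exact indel size
        # an inverted chain covering the gap in BOTH genomes (and a gap of
        # conserved size) marks an in-place inversion; a one-sided inverted
        # match is just homology to another inverted repeat copy
        cov_inv <- FALSE
        if (nrow(inv) > 0 && gap_a > 0 && gap_b > 0.5 * gap_a &&
            gap_a > 0.5 * gap_b) {
          ov_a <- pmax(0, pmin(inv$end_a, fw$start_a[j + 1L]) -
                         pmax(inv$start_a, fw$end_a[j]))
          ov_b <- pmax(0, pmin(inv$end_b, fw$start_b[j + 1L]) -
                         pmax(inv$start_b, fw$end_b[j]))
          cov_inv <- any(ov_a > 0.8 * gap_a & ov_b > 0.8 * gap_b)
        }
        if (cov_inv) {
          if (gap_a >= min_sv) {
            svs[[length(svs) + 1L]] <- sv_row(
              "inversion", ca, fw$end_a[j], fw$start_a[j + 1L], cb,
              fw$end_b[j], fw$start_b[j + 1L], gap_a)
          }
        } else if (jump >= min_sv) {
          svs[[length(svs) + 1L]] <- sv_row(
            "deletion", ca, fw$end_a[j], fw$start_a[j + 1L], cb,
            fw$end_b[j], fw$start_b[j + 1L], jump)
        } else if (-jump >= min_sv) {
          svs[[length(svs) + 1L]] <- sv_row(
            "insertion_in_b", ca, fw$end_a[j], fw$start_a[j + 1L], cb,
            fw$end_b[j], fw$start_b[j + 1L], -jump)
        } else if (gap_a >= min_sv && gap_b >= min_sv) {
          svs[[length(svs) + 1L]] <- sv_row(
            "substitution_block", ca, fw$end_a[j], fw$start_a[j + 1L], cb,
            fw$end_b[j], fw$start_b[j + 1L], max(gap_a, gap_b))
        } else if (jump != 0L) {
          n_small <- n_small + 1L
        }
      }
    }
    # contig termini
    la <- nchar(a$contigs[[ca]]); lb <- nchar(b$contigs[[cb]])
    head_jump <- fw$start_a[1] - fw$start_b[1]
    if (head_jump >= min_sv) {
      svs[[length(svs) + 1L]] <- sv_row("deletion", ca, 0L, fw$start_a[1],
                                        cb, 0L, fw$start_b[1], head_jump)
    } else if (-head_jump >= min_sv) {
      svs[[length(svs) + 1L]] <- sv_row("insertion_in_b", ca, 0L,
                                        fw$start_a[1], cb, 0L,
                                        fw$start_b[1], -head_jump)
    }
    nfw <- nrow(fw)
    tail_jump <- (la - fw$end_a[nfw]) - (lb - fw$end_b[nfw])
    if (tail_jump >= min_sv) {
      svs[[length(svs) + 1L]] <- sv_row("deletion", ca, fw$end_a[nfw], la,
                                        cb, fw$end_b[nfw], lb, tail_jump)
    } else if (-tail_jump >= min_sv) {
      svs[[length(svs) + 1L]] <- sv_row("insertion_in_b", ca, fw$end_a[nfw],
                                        la, cb, fw$end_b[nfw], lb,
                                        -tail_jump)
    }
  }
  out <- if (length(svs)) do.call(rbind, svs) else empty_sv_df()
  out <- out[order(out$contig_a, out$start_a, out$sv_type), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_small_indels") <- n_small
  out
}

# is [start-L, start) the reverse complement of [end, end+L) within tol?
ir_flanked_at <- function(seq, start, end, min_ir, tol_frac = 0.02) {
  L <- min_ir
  if (start - L < 0 || end + L > nchar(seq)) return(FALSE)
  u <- subseq_chr(seq, start - L, start)
  v <- revcomp(subseq_chr(seq, end, end + L))
  al <- cpp_banded_align(u, v, 16L)
  al$edit <= tol_frac * L
}

#' Classify structural variants with read and repeat evidence
#'
#' Applies the evidence decision table, in order: (1) an inversion whose
#' breakpoints fall at an inverted-repeat pair is a mating-type switch;
#' (2) a segment present in `a` and absent in `b` whose junctions in `a`
#' are spanned by long reads and which overlaps duplicated/repeat content
#' (duplicated segment, LTR element, tandem array) is a collapsed-repeat
#' candidate misassembly in `b`; (3) such a segment with full junction
#' support and no repeat overlap is a true SV; (4) a segment present only
#' in `b` stays unclassified unless junction spanning in `a` fails, which
#' marks a candidate misassembly in `a`. Reads are assumed to come from
#' genome `a`, so labels for `b` are candidates, not verdicts.
#'
#' @param svs data.frame from [call_svs()].
#' @param a,b The two `Genome`s.
#' @param long_alignments_a `Alignments` of long reads (from strain `a`)
#'   against genome `a`.
#' @param repeats_a list with any of `arrays`, `ltr`, `lds` data.frames
#'   carrying `contig`/`start`/`end` intervals in genome `a` (the `ltr`
#'   table may use `ltr5_start`/`ltr3_end`; the `lds` table uses
#'   `contig_a`/`start_a`/`end_a` and `contig_b`/... for both copies).
#' @param policy A [curation_policy()].
#' @param min_ir Minimum inverted-repeat length for the mating-type rule.
#' @return `svs` with `classification` and evidence columns filled.
#' @export
classify_svs <- function(svs, a, b, long_alignments_a, repeats_a = list(),
                         policy = curation_policy(), min_ir = 1500L) {
  if (nrow(svs) == 0) return(svs)
  rep_iv <- list()
  if (!is.null(repeats_a$arrays) && nrow(repeats_a$arrays) > 0) {
    rep_iv[[length(rep_iv) + 1L]] <- data.frame(
      contig = repeats_a$arrays$contig, start = repeats_a$arrays$start,
      end = repeats_a$arrays$end, kind = "TR_array",
      stringsAsFactors = FALSE)
  }
  if (!is.null(repeats_a$ltr) && nrow(repeats_a$ltr) > 0) {
    lt <- repeats_a$ltr
    st <- if ("ltr5_start" %in% names(lt)) lt$ltr5_start else lt$start
    en <- if ("ltr3_end" %in% names(lt)) lt$ltr3_end else lt$end
    rep_iv[[length(rep_iv) + 1L]] <- data.frame(
      contig = lt$contig, start = st, end = en, kind = "LTR_rt",
      stringsAsFactors = FALSE)
  }
  if (!is.null(repeats_a$lds) && nrow(repeats_a$lds) > 0) {
    ld <- repeats_a$lds
    rep_iv[[length(rep_iv) + 1L]] <- data.frame(
      contig = c(ld$contig_a, ld$contig_b),
      start = c(ld$start_a, ld$start_b), end = c(ld$end_a, ld$end_b),
      kind = "LDS", stringsAsFactors = FALSE)
  }
  rep_iv <- if (length(rep_iv)) do.call(rbind, rep_iv) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               kind = character(0), stringsAsFactors = FALSE)
  # repeat classes in priority order for reporting
  prio <- c(LDS = 1, LTR_rt = 2, TR_array = 3)
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    if (sv$sv_type == "inversion") {
      flanked <- ir_flanked_at(a$contigs[[sv$contig_a]], sv$start_a,
                               sv$end_a, min_ir)
      svs$ir_flanked[i] <- flanked
      if (flanked) svs$classification[i] <- "mat_switch"
      next
    }
    jl <- verify_junction_support(
      list(contig = sv$contig_a, position = sv$start_a),
      long_alignments_a, policy, assembly = a)
    jr <- verify_junction_support(
      list(contig = sv$contig_a, position = sv$end_a),
      long_alignments_a, policy, assembly = a)
    svs$n_spanning[i] <- min(jl$n_spanning, jr$n_spanning)
    support <- jl$pass && jr$pass
    if (sv$sv_type %in% c("deletion", "translocation")) {
      hit <- rep_iv[rep_iv$contig == sv$contig_a &
                      overlaps(rep_iv$start, rep_iv$end, sv$start_a,
                               sv$end_a), , drop = FALSE]
      svs$overlaps_repeat[i] <- nrow(hit) > 0
      if (nrow(hit) > 0) {
        svs$repeat_kind[i] <- hit$kind[which.min(prio[hit$kind])]
      }
      if (support && nrow(hit) > 0) {
        svs$classification[i] <- "candidate_misassembly_in_b"
      } else if (support) {
        svs$classification[i] <- "true_sv"
      }
    } else if (sv$sv_type == "insertion_in_b") {
      svs$overlaps_repeat[i] <- FALSE
      if (!support) svs$classification[i] <- "candidate_misassembly_in_a"
    }
  }
  svs
}

#' Detect a mating-type inversion between two assemblies
#'
#' Finds inverted-repeat pairs of at least `min_ir` bases in genome `a`
#' (near-reverse-complement repeat discovery by k-mer anchoring of each
#' contig against its own reverse complement), then tests whether the
#' region between the repeats appears reverse-complemented in genome `b`
#' (located by unique flanking sequence) within `max_edits`.
#'
#' @param a,b `Genome` objects.
#' @param min_ir Minimum inverted-repeat length (bp).
#' @param max_edits Maximum edits between `b`'s region and the reverse
#'   complement of `a`'s.
#' @return A list of class `MatLocus` (fields `contig`, `ir1`, `ir2`,
#'   `invertible` as 0-based intervals, `ir_length`, `orientation_in_a`,
#'   `orientation_in_b`), or `NULL` when no inverted region is found.
#' @export
detect_mat_inversion <- function(a, b, min_ir = 1500L, max_edits = 5L) {
  for (nm in names(a$contigs)) {
    s <- a$contigs[[nm]]
    n <- nchar(s)
    anc <- cpp_kmer_matches(s, revcomp(s), 21L, 4L)
    if (nrow(anc) == 0) next
    chains <- chain_anchors(anc$apos, anc$bpos, 21L, max_diag_gap = 32L,
                            min_anchors = 10L, max_pos_gap = 5000L)
    for (ch in chains) {
      i1 <- c(ch$a_start, ch$a_end)
      i2 <- c(n - ch$b_end, n - ch$b_start)
      if (i1[1] >= i2[1]) next                  # mirrored duplicate
      if (i1[2] - i1[1] < min_ir) next
      if (i2[1] - i1[2] < 1000L) next           # need a region between IRs
      inv_a <- subseq_chr(s, i1[2], i2[1])
      # locate the locus in b by unique upstream flank
      if (i1[1] < 80L) next
      ua <- subseq_chr(s, i1[1] - 80L, i1[1])
      hit <- NULL
      for (cb in names(b$contigs)) {
        m <- Biostrings::matchPattern(ua,
                                      Biostrings::DNAString(b$contigs[[cb]]))
        if (length(m) == 1) { hit <- list(contig = cb,
                                          pos = Biostrings::end(m)[1]); break }
      }
      if (is.null(hit)) next
      ir_len <- i1[2] - i1[1]
      b_inv_start <- hit$pos + ir_len       # 0-based end of flank == hit$pos
      b_inv_end <- b_inv_start + (i2[1] - i1[2])
      if (b_inv_end > nchar(b$contigs[[hit$contig]])) next
      inv_b <- subseq_chr(b$contigs[[hit$contig]], b_inv_start, b_inv_end)
      d_fwd <- cpp_banded_align(inv_a, inv_b, 16L)$edit
      if (d_fwd <= max_edits) next              # same orientation: no switch
      d_rc <- cpp_banded_align(revcomp(inv_a), inv_b, 16L)$edit
      if (d_rc <= max_edits) {
        return(structure(list(
          contig = nm, ir1 = i1, ir2 = i2,
          invertible = c(i1[2], i2[1]), ir_length = ir_len,
          orientation_in_a = "alpha", orientation_in_b = "a",
          contig_b = hit$contig, edits = d_rc), class = "MatLocus"))
      }
    }
  }
  NULL
}

#' Estimate mating-type switching frequency from long reads
#'
#' A read is informative when it spans one of the two outer
#' flank/inverted-repeat junctions with `junction_flank` bases on both
#' sides of the repeat; each informative read votes for the orientation
#' (alpha = genome `a`'s) whose junction reference it matches with fewer
#' edits. The switch frequency is minority votes over total votes, with a
#' binomial 95% confidence interval.
#'
#' @param reads A `ReadSet` of long reads.
#' @param mat A `MatLocus` from [detect_mat_inversion()].
#' @param assembly The `Genome` the locus was detected in (orientation
#'   alpha).
#' @param policy A [curation_policy()].
#' @return The `MatLocus` with `per_read_votes`, `switch_frequency` and
#'   `ci95` filled; `switch_frequency` is `NA` when no read is informative.
#' @export
estimate_mat_switch_frequency <- function(reads, mat, assembly,
                                          policy = curation_policy()) {
  stopifnot(inherits(reads, "ReadSet"), inherits(mat, "MatLocus"))
  s <- assembly$contigs[[mat$contig]]
  f <- policy$junction_flank
  irl <- mat$ir_length
  inv <- mat$invertible
  # left junction: outer flank + IR1 + first f bases of the invertible
  # region (alpha) or of its reverse complement (a)
  refs <- list()
  refs$left_alpha <- subseq_chr(s, mat$ir1[1] - f, mat$ir1[2] + f)
  refs$left_a <- paste0(subseq_chr(s, mat$ir1[1] - f, mat$ir1[2]),
                        revcomp(subseq_chr(s, inv[2] - f, inv[2])))
  refs$right_alpha <- subseq_chr(s, mat$ir2[1] - f, mat$ir2[2] + f)
  refs$right_a <- paste0(revcomp(subseq_chr(s, inv[1], inv[1] + f)),
                         subseq_chr(s, mat$ir2[1], mat$ir2[2] + f))
  # anchor k-mers in the outer flanks (shared between the two orientations)
  anchors <- list(
    left = list(at = 10L, seq = substr(refs$left_alpha, 11L, 41L)),
    right = list(at = nchar(refs$right_alpha) - 41L,
                 seq = substr(refs$right_alpha,
                              nchar(refs$right_alpha) - 40L,
                              nchar(refs$right_alpha) - 10L)))
  votes <- c(alpha = 0L, a = 0L, uninformative = 0L)
  reflen <- irl + 2L * f
  for (rd in reads$seqs) {
    if (nchar(rd) < policy$long_read_min) next
    voted <- FALSE
    for (q in list(rd, revcomp(rd))) {
      for (side in c("left", "right")) {
        an <- anchors[[side]]
        p <- regexpr(an$seq, q, fixed = TRUE)[[1]]
        if (p < 0) next
        seg_start <- p - 1L - an$at   # 0-based start of ref window in read
        if (seg_start < 0 || seg_start + reflen > nchar(q)) next
        seg <- subseq_chr(q, seg_start, seg_start + reflen)
        ra <- refs[[paste0(side, "_alpha")]]
        rb <- refs[[paste0(side, "_a")]]
        d_alpha <- cpp_banded_align(ra, seg, 48L)$edit
        d_a <- cpp_banded_align(rb, seg, 48L)$edit
        if (d_alpha < d_a) {
          votes["alpha"] <- votes["alpha"] + 1L
        } else if (d_a < d_alpha) {
          votes["a"] <- votes["a"] + 1L
        } else {
          votes["uninformative"] <- votes["uninformative"] + 1L
        }
        voted <- TRUE
        break
      }
      if (voted) break
    }
    if (!voted) votes["uninformative"] <- votes["uninformative"] + 1L
  }
  total <- votes[["alpha"]] + votes[["a"]]
  mat$per_read_votes <- as.list(votes)
  if (total == 0) {
    mat$switch_frequency <- NA_real_
    mat$ci95 <- c(NA_real_, NA_real_)
  } else {
    minority <- min(votes[["alpha"]], votes[["a"]])
    mat$switch_frequency <- minority / total
    mat$ci95 <- as.numeric(stats::binom.test(minority, total)$conf.int)
  }
  mat
}
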
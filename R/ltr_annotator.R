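# LTR retrotransposon annotation: paired near-identical LTR discovery by
# k-mer anchoring, target-site motif checks, internal ORF integrity tiers,
# and copy-to-copy difference accounting.

#' Find candidate paired-LTR repeats
#'
#' Pairs of co-oriented near-identical repeats whose lengths fall in
#' `len_range` and whose internal spacing falls in `spacing_range`, found by
#' self k-mer anchoring and maximal exact extension; each repeat copy is
#' used in at most one pair (greedy by identity, then span, then leftmost
#' coordinate).
#'
#' @param g A `Genome`.
#' @param len_range LTR length range (bp).
#' @param spacing_range Range of the internal distance between the two LTRs
#'   (bp).
#' @param min_identity Minimum identity between the paired LTRs.
#' @param k Anchor k-mer length.
#' @return data.frame with `contig`, `ltr5_start`, `ltr5_end`,
#'   `ltr3_start`, `ltr3_end`, `ltr_length`, `spacing`, `ltr_identity`.
#' @export
find_ltr_pairs <- function(g, len_range = c(200L, 600L),
                           spacing_range = c(2000L, 8000L),
                           min_identity = 0.95, k = 21L) {
  stopifnot(inherits(g, "Genome"))
  d_range <- c(spacing_range[1] + len_range[1],
               spacing_range[2] + len_range[2])
  cands <- list()
  for (nm in names(g$contigs)) {
    s <- g$contigs[[nm]]
    anc <- cpp_kmer_matches(s, s, as.integer(k), 8L)
    sel <- anc$bpos > anc$apos &
      (anc$bpos - anc$apos) >= d_range[1] &
      (anc$bpos - anc$apos) <= d_range[2]
    if (!any(sel)) next
    chains <- chain_anchors(anc$apos[sel], anc$bpos[sel], k,
                            max_diag_gap = 16L, min_anchors = 3L,
                            max_pos_gap = 200L)
    for (ch in chains) {
      as0 <- ch$a_start; ae <- ch$a_end
      bs0 <- ch$b_start; be <- ch$b_end
      while (as0 > 0 && bs0 > 0 &&
             substr(s, as0, as0) == substr(s, bs0, bs0)) {
        as0 <- as0 - 1L; bs0 <- bs0 - 1L
      }
      n <- nchar(s)
      while (ae < n && be < n &&
             substr(s, ae + 1L, ae + 1L) == substr(s, be + 1L, be + 1L)) {
        ae <- ae + 1L; be <- be + 1L
      }
      len_a <- ae - as0
      spacing <- bs0 - ae
      if (len_a < len_range[1] || len_a > len_range[2]) next
      if (spacing < spacing_range[1] || spacing > spacing_range[2]) next
      al <- cpp_banded_align(substr(s, as0 + 1L, ae),
                             substr(s, bs0 + 1L, be),
                             abs((ae - as0) - (be - bs0)) + 16L)
      identity <- 1 - (al$n_mismatch + al$n_gap_columns) / al$columns
      if (identity < min_identity) next
      cands[[length(cands) + 1L]] <- data.frame(
        contig = nm, ltr5_start = as0, ltr5_end = ae, ltr3_start = bs0,
        ltr3_end = be, ltr_length = len_a, spacing = spacing,
        ltr_identity = identity, stringsAsFactors = FALSE)
    }
  }
  if (length(cands) == 0) {
    return(data.frame(contig = character(0), ltr5_start = integer(0),
                      ltr5_end = integer(0), ltr3_start = integer(0),
                      ltr3_end = integer(0), ltr_length = integer(0),
                      spacing = integer(0), ltr_identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, cands)
  df <- df[order(-df$ltr_identity,
                 -(df$ltr3_end - df$ltr5_start), df$ltr5_start), ,
           drop = FALSE]
  used <- list()
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    iv <- list(c(df$contig[i], df$ltr5_start[i], df$ltr5_end[i]),
               c(df$contig[i], df$ltr3_start[i], df$ltr3_end[i]))
    clash <- any(vapply(used, function(u) {
      any(vapply(iv, function(v) {
        u[1] == v[1] && overlaps(as.integer(u[2]), as.integer(u[3]),
                                 as.integer(v[2]), as.integer(v[3]))
      }, logical(1)))
    }, logical(1)))
    if (clash) { keep[i] <- FALSE; next }
    used <- c(used, iv)
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$contig, df$ltr5_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Scan a sequence for open reading frames in six frames
#'
#' @param seq DNA string.
#' @param min_aa Minimum ORF length (aa) to report.
#' @return data.frame `strand`, `frame`, `start`, `end` (0-based half-open,
#'   in the input sequence's forward coordinates for `+`; in the reverse
#'   complement's coordinates for `-`), `aa_length`.
#' @export
orf_scan <- function(seq, min_aa = 100L) {
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    n <- nchar(s)
    for (fr in 0:2) {
      if (n - fr < 6) next
      cs <- seq(fr + 1L, n - 2L, by = 3L)
      cods <- substring(s, cs, cs + 2L)
      stops <- which(cods %in% STOP_CODONS)
      starts <- which(cods == "ATG")
      prev <- 0L
      for (st in stops) {
        cand <- starts[starts > prev & starts < st]
        if (length(cand)) {
          aa <- st - cand[1]
          if (aa >= min_aa) {
            res[[length(res) + 1L]] <- data.frame(
              strand = strand, frame = fr, start = cs[cand[1]] - 1L,
              end = cs[st] + 2L, aa_length = aa, stringsAsFactors = FALSE)
          }
        }
        prev <- st
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa_length = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(-out$aa_length), , drop = FALSE]
}

#' Annotate LTR retrotransposon elements
#'
#' Resolves the element strand by which orientation places `flank5`
#' immediately 5' of the upstream LTR and `flank3` immediately 3' of the
#' downstream LTR (exact match, zero gap); scans the internal region for
#' ORFs in six frames. An element is `structural_intact` when both LTRs and
#' the internal region are present, and `coding_intact` when a single ORF of
#' at least `min_aa` amino acids covers the internal region.
#'
#' @param pairs data.frame from [find_ltr_pairs()].
#' @param g The `Genome`.
#' @param flank5,flank3 Target-site motifs.
#' @param min_aa Minimum polyprotein length (aa) for coding intactness.
#' @return data.frame of elements with flank/strand/ORF annotations and
#'   per-LTR GC content; the full ORF tables are attached as the `orfs`
#'   attribute (a list parallel to rows).
#' @export
annotate_ltr_elements <- function(pairs, g, flank5 = "TCTTG",
                                  flank3 = "CAACA", min_aa = 1000L) {
  if (nrow(pairs) == 0) {
    out <- cbind(pairs, strand = character(0), flank_ok = logical(0),
                 internal_start = integer(0), internal_end = integer(0),
                 structural_intact = logical(0), coding_intact = logical(0),
                 n_orfs = integer(0), max_orf_aa = integer(0),
                 ltr_gc = numeric(0))
    attr(out, "orfs") <- list()
    return(out)
  }
  fl <- nchar(flank5)
  orfs_list <- vector("list", nrow(pairs))
  ann <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    s <- g$contigs[[p$contig]]
    up <- if (p$ltr5_start >= fl) {
      subseq_chr(s, p$ltr5_start - fl, p$ltr5_start)
    } else ""
    dn <- if (p$ltr3_end + nchar(flank3) <= nchar(s)) {
      subseq_chr(s, p$ltr3_end, p$ltr3_end + nchar(flank3))
    } else ""
    if (up == flank5 && dn == flank3) {
      strand <- "+"; flank_ok <- TRUE
    } else if (up == revcomp(flank3) && dn == revcomp(flank5)) {
      strand <- "-"; flank_ok <- TRUE
    } else {
      strand <- "+"; flank_ok <- FALSE
    }
    internal <- subseq_chr(s, p$ltr5_end, p$ltr3_start)
    if (strand == "-") internal <- revcomp(internal)
    orfs <- orf_scan(internal, min_aa = 100L)
    orfs_list[[i]] <<- orfs
    long <- orfs$aa_length >= min_aa
    ltr_seq <- subseq_chr(s, p$ltr5_start, p$ltr5_end)
    gc <- nchar(gsub("[AT]", "", ltr_seq)) / nchar(ltr_seq)
    data.frame(strand = strand, flank_ok = flank_ok,
               internal_start = p$ltr5_end, internal_end = p$ltr3_start,
               structural_intact = TRUE,
               coding_intact = any(long),
               n_orfs = nrow(orfs),
               max_orf_aa = if (nrow(orfs)) max(orfs$aa_length) else 0L,
               ltr_gc = gc, stringsAsFactors = FALSE)
  })
  out <- cbind(pairs, do.call(rbind, ann))
  rownames(out) <- NULL
  attr(out, "orfs") <- orfs_list
  out
}

element_seq <- function(el, g) {
  s <- subseq_chr(g$contigs[[el$contig]], el$ltr5_start, el$ltr3_end)
  if (!is.null(el$strand) && el$strand == "-") s <- revcomp(s) else s
}

# an insertion inside repeated/chance-matching context has several
# equivalent placements; slide it to the one on a codon boundary of the
# anchoring ORF so the translated peptide is in frame
slide_to_frame <- function(sa, pos, X, frame_anchor) {
  cands <- list(list(pos = pos, X = X))
  p <- pos; Y <- X
  repeat {
    ch <- substr(sa, p + 1L, p + 1L)
    if (nchar(ch) == 0 || ch != substr(Y, 1L, 1L) || p > pos + 60L) break
    Y <- paste0(substr(Y, 2L, nchar(Y)), ch)
    p <- p + 1L
    cands[[length(cands) + 1L]] <- list(pos = p, X = Y)
  }
  p <- pos; Y <- X
  repeat {
    if (p <= 0L || p < pos - 60L) break
    ch <- substr(sa, p, p)
    if (ch != substr(Y, nchar(Y), nchar(Y))) break
    Y <- paste0(ch, substr(Y, 1L, nchar(Y) - 1L))
    p <- p - 1L
    cands[[length(cands) + 1L]] <- list(pos = p, X = Y)
  }
  for (cd in cands) {
    if ((cd$pos - frame_anchor) %% 3L == 0L) return(cd)
  }
  cands[[1L]]
}

#' Compare two LTR elements
#'
#' Global pairwise alignment of the full element sequences; reports SNP
#' counts and insertion/deletion events (positions in element-a
#' coordinates), translating in-frame insertions.
#'
#' @param a,b Single-row element data.frames (from
#'   [annotate_ltr_elements()]).
#' @param g_a,g_b Genomes carrying the elements (`g_b` defaults to `g_a`).
#' @return list of class `ElementDiff`: `snps`, `insertions` (data.frame
#'   `position`, `length`, `peptide`), `deletions`, `orf_breaking`,
#'   `identity`.
#' @export
compare_elements <- function(a, b, g_a, g_b = g_a) {
  sa <- element_seq(a, g_a)
  sb <- element_seq(b, g_b)
  # codon-frame anchor from element a's main ORF (element coordinates)
  frame_anchor <- NA_integer_
  if (!is.null(a$internal_start)) {
    int_off <- a$internal_start - a$ltr5_start
    if (isTRUE(a$strand == "-")) {
      int_off <- a$ltr3_end - a$internal_end
    }
    int_seq <- substr(sa, int_off + 1L, int_off + (a$internal_end -
                                                    a$internal_start))
    orfs <- orf_scan(int_seq, min_aa = 300L)
    orfs <- orfs[orfs$strand == "+", , drop = FALSE]
    if (nrow(orfs) > 0) frame_anchor <- int_off + orfs$start[1]
  }
  al <- cpp_banded_align(sa, sb, abs(nchar(sa) - nchar(sb)) + 64L)
  ops <- parse_cigar(al$cigar)
  apos <- 0L; bpos <- 0L
  snps <- 0L
  ins <- list(); del <- list()
  for (r in seq_len(nrow(ops))) {
    len <- ops$len[r]
    if (ops$op[r] == "M") {
      va <- substring(sa, apos + 1L, apos + len)
      vb <- substring(sb, bpos + 1L, bpos + len)
      if (va != vb) {
        snps <- snps + sum(strsplit(va, "")[[1]] != strsplit(vb, "")[[1]])
      }
      apos <- apos + len; bpos <- bpos + len
    } else if (ops$op[r] == "I") {     # present in b, absent in a
      iseq <- substring(sb, bpos + 1L, bpos + len)
      ipos <- apos
      if (len %% 3L == 0L && !is.na(frame_anchor)) {
        sl <- slide_to_frame(sa, apos, iseq, frame_anchor)
        ipos <- sl$pos
        iseq <- sl$X
      }
      pep <- if (len %% 3L == 0L) {
        as.character(Biostrings::translate(Biostrings::DNAString(iseq),
                                           no.init.codon = TRUE))
      } else NA_character_
      ins[[length(ins) + 1L]] <- data.frame(position = ipos, length = len,
                                            peptide = pep,
                                            stringsAsFactors = FALSE)
      bpos <- bpos + len
    } else if (ops$op[r] == "D") {     # present in a, absent in b
      del[[length(del) + 1L]] <- data.frame(position = apos, length = len,
                                            stringsAsFactors = FALSE)
      apos <- apos + len
    }
  }
  insd <- if (length(ins)) do.call(rbind, ins) else
    data.frame(position = integer(0), length = integer(0),
               peptide = character(0), stringsAsFactors = FALSE)
  deld <- if (length(del)) do.call(rbind, del) else
    data.frame(position = integer(0), length = integer(0),
               stringsAsFactors = FALSE)
  frameshift <- any(c(insd$length, deld$length) %% 3L != 0L)
  coding_flip <- isTRUE(a$coding_intact) != isTRUE(b$coding_intact)
  structure(list(snps = snps, insertions = insd, deletions = deld,
                 orf_breaking = frameshift || coding_flip,
                 identity = 1 - (al$n_mismatch + al$n_gap_columns) /
                   al$columns),
            class = "ElementDiff")
}

#' Classify retroelement type from protein-domain gene order
#'
#' Copia-group elements carry integrase (IN) before reverse transcriptase
#' (RT); the order PR, IN, RT, RH specifically marks the Ty5 type. IN after
#' RT marks gypsy-like elements; anything unresolvable is `unknown`.
#'
#' @param domains data.frame with columns `name` (among GAG, PR, IN, RT,
#'   RH) and `start` (ordering coordinate).
#' @return One of `"Ty5"`, `"gypsy-like"`, `"unknown"`.
#' @export
classify_gene_order <- function(domains) {
  stopifnot(is.data.frame(domains), all(c("name", "start") %in%
                                          names(domains)))
  if (anyDuplicated(domains$name)) stop("duplicate domain names")
  need <- c("PR", "IN", "RT", "RH")
  if (!all(need %in% domains$name)) return("unknown")
  ord <- domains$name[order(domains$start)]
  ord <- ord[ord %in% need]
  if (identical(ord, c("PR", "IN", "RT", "RH"))) return("Ty5")
  if (which(ord == "IN") > which(ord == "RT")) return("gypsy-like")
  "unknown"
}
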